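# Cluster detection over ordered gene tables, flanking-amylase counting,
# tendamistat flags.

# small hand-built contig: roles placed at chosen indices, fillers elsewhere
mk_contig <- function(n, roles_at = list(), genome = "g1", contig = "c1") {
  roles <- rep("", n)
  for (i in seq_along(roles_at)) roles[roles_at[[i]] + 1L] <- names(roles_at)[i]
  data.frame(genome_id = genome, contig_id = contig, gene_index = 0:(n - 1),
             protein_id = sprintf("%s_%s_p%03d", genome, contig, 1:n),
             roles = roles, at_contig_edge = c(TRUE, rep(FALSE, n - 2), TRUE),
             stringsAsFactors = FALSE)
}

gac15 <- function(start) {
  r <- list()
  roles <- paste0("gac", c("A", "V", "W", "X", "Y", "U", "S", "R", "K", "I", "Q", "C", "J", "M", "O"))
  for (i in seq_along(roles)) r[[roles[i]]] <- start + i - 1L
  r
}

test_that("a contiguous core-gene run yields one complete locus", {
  g <- mk_contig(40, gac15(10))
  loci <- find_bgc_loci(g, acarbose_query())
  expect_equal(nrow(loci), 1)
  expect_equal(loci$n_required, 15)
  expect_equal(c(loci$span_start, loci$span_end), c(10, 24))
  expect_false(loci$truncated_at_contig_edge)
})

test_that("required_fraction is a sharp threshold and monotone", {
  ra <- gac15(10)
  ra$gacA <- NULL  # 14 of 15 core genes present
  g <- mk_contig(40, ra)
  expect_equal(nrow(find_bgc_loci(g, acarbose_query(required_fraction = 1.0))), 0)
  expect_equal(nrow(find_bgc_loci(g, acarbose_query(required_fraction = 0.9))), 1)

  # lowering required_fraction never loses loci
  full <- mk_contig(40, gac15(5))
  for (f in c(1, 0.8, 0.5, 0.2)) {
    expect_gte(nrow(find_bgc_loci(full, acarbose_query(required_fraction = f))), 1)
  }
})

test_that("runs split at gaps wider than max_gene_gap", {
  # two complete core runs separated by 50 unrelated genes
  g <- mk_contig(120, c(gac15(5), gac15(70)))
  loci <- find_bgc_loci(g, acarbose_query(max_gene_gap = 5))
  expect_equal(nrow(loci), 2)
  expect_equal(loci$span_start, c(5, 70))

  # with a gap wide enough the runs merge into one locus
  merged <- find_bgc_loci(g, acarbose_query(max_gene_gap = 60))
  expect_equal(nrow(merged), 1)

  expect_error(find_bgc_loci(g[rev(seq_len(nrow(g))), ], acarbose_query()), "sorted")
})

test_that("strandless model: reversing the contig preserves loci", {
  g <- mk_contig(60, c(gac15(20), list(amylase = c(36, 38))))
  fwd <- find_bgc_loci(g, acarbose_query())
  rev_g <- g
  rev_g$gene_index <- max(g$gene_index) - g$gene_index
  rev_g <- rev_g[order(rev_g$gene_index), ]
  bwd <- find_bgc_loci(rev_g, acarbose_query())
  expect_equal(nrow(bwd), nrow(fwd))
  expect_equal(bwd$span_end - bwd$span_start, fwd$span_end - fwd$span_start)
  expect_equal(count_flanking_amylases(bwd[1, ], rev_g, 10),
               count_flanking_amylases(fwd[1, ], g, 10))
})

test_that("flanking-amylase counts honor the window and contig clipping", {
  # adjacent optional amylases at 35-36 extend the span to [20,36]; the
  # distant pair at 46/47 is beyond max_gene_gap and stays outside
  g <- mk_contig(80, c(gac15(20), list(amylase = c(35, 36, 46, 47))))
  loci <- find_bgc_loci(g, acarbose_query())
  expect_equal(nrow(loci), 1)
  expect_equal(c(loci$span_start, loci$span_end), c(20, 36))
  expect_equal(count_flanking_amylases(loci[1, ], g, flank_genes = 10), 3)
  expect_equal(count_flanking_amylases(loci[1, ], g, flank_genes = 11), 4)
  expect_equal(count_flanking_amylases(loci[1, ], g, flank_genes = 0), 2)

  # locus at the contig start: left flank clipped without error, flagged
  g0 <- mk_contig(40, gac15(0))
  l0 <- find_bgc_loci(g0, acarbose_query())
  expect_true(l0$truncated_at_contig_edge)
  expect_equal(count_flanking_amylases(l0[1, ], g0, flank_genes = 10), 0)
})

test_that("tendamistat flags follow the E-value cutoff strictly", {
  hits <- data.frame(protein_id = c("x1", "x2", "x3"),
                     genome_id = c("g1", "g2", "g3"),
                     e_value = c(1e-12, 1e-9, 1e-10), score = c(100, 20, 60))
  fl <- filter_tendamistat_hits(hits, cutoff = 1e-10, genomes = c("g1", "g2", "g3", "g4"))
  expect_equal(fl$has_tendamistat, c(TRUE, FALSE, TRUE, FALSE))  # cutoff is inclusive
  expect_false(any(filter_tendamistat_hits(hits[0, ], genomes = c("g1", "g2"))$has_tendamistat))
  hits$e_value[1] <- 0
  expect_error(filter_tendamistat_hits(hits), "strictly positive")
})

test_that("synthetic cohorts: planted flags and flanking counts are recovered", {
  co <- generate_cohort(cohort_params(n_genomes = 50, p_bgc = 0.3, seed = 29))
  loci <- find_bgc_loci(co$genes, acarbose_query())
  flagged <- unique(loci$genome_id)
  expect_setequal(flagged, co$truth$genome_id[co$truth$has_bgc])
  expect_true(all(loci$n_required == 15))
  for (i in seq_len(nrow(loci))) {
    planted <- co$truth$planted_flanking[co$truth$genome_id == loci$genome_id[i]]
    expect_equal(count_flanking_amylases(loci[i, ], co$genes, flank_genes = 10), planted)
  }
  # loci are disjoint within each contig
  if (nrow(loci) > 1) {
    by_contig <- split(loci, paste(loci$genome_id, loci$contig_id))
    for (lc in by_contig) {
      if (nrow(lc) < 2) next
      lc <- lc[order(lc$span_start), ]
      expect_true(all(lc$span_start[-1] > lc$span_end[-nrow(lc)]))
    }
  }
})
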