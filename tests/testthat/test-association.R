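# Cohort summaries, count/binary associations, the enrichment scan and the
# substitution census.

mk_amy <- function(genome, clade) {
  data.frame(protein_id = sprintf("p%03d", seq_along(genome)), genome_id = genome,
             clade = clade, domain_names = "", contig_id = "c1",
             gene_index = seq_along(genome) - 1L, stringsAsFactors = FALSE)
}

test_that("cohort summaries count per clade and preserve totals", {
  meta <- data.frame(genome_id = c("g1", "g2", "g3", "g4"), genome_size_bp = 8e6)
  amy <- mk_amy(c("g1", "g1", "g2", "g4"),
                c("pullulanase", "pullulanase", "alpha14", "cmd_like"))
  s <- summarize_cohort(amy, genome_metadata = meta)
  expect_equal(s$total_amylases, c(2L, 1L, 0L, 1L))
  expect_equal(prevalence_pct(s, "n_pullulanase"), 25)
  expect_equal(prevalence_pct(s, "n_alpha14"), 25)
  expect_equal(prevalence_pct(s, "n_cmd_like"), 25)
  expect_equal(s$has_cmd, c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(sum(s$total_amylases), nrow(amy))

  s0 <- summarize_cohort(amy[0, ], genome_metadata = meta)
  expect_equal(sum(s0$total_amylases), 0)

  expect_error(summarize_cohort(mk_amy("gX", "alpha14"), genome_metadata = meta),
               "unknown genome.*gX")

  # synthetic cohort: summaries equal the generator's planted counts
  co <- generate_cohort(cohort_params(n_genomes = 30, p_bgc = 0.2, seed = 19))
  kept <- filter_secreted_amylases(co$cazyme, co$secretion, co$domains, genes = co$genes)$kept
  s <- summarize_cohort(kept, genome_metadata = co$genomes)
  expect_equal(s$total_amylases, co$truth$total_amylases)
  expect_equal(s$n_pullulanase, co$truth$n_pullulanase)
  expect_equal(s$n_cmd_like, co$truth$n_cmd_like)
  expect_equal(sum(s$total_amylases), nrow(co$amylases))
})

test_that("count association is signed for the flagged group and guards empties", {
  s <- data.frame(genome_id = sprintf("g%d", 1:10),
                  total_amylases = c(rep(6, 3), rep(0, 7)),
                  flag = c(rep(TRUE, 3), rep(FALSE, 7)))
  r <- count_association(s, "flag", "total_amylases")
  expect_equal(r$effect_size_r, 1)
  s$flag <- FALSE
  expect_error(count_association(s, "flag", "total_amylases"), "group empty.*TRUE")
  s$flag <- TRUE
  expect_error(count_association(s, "flag", "total_amylases"), "group empty.*FALSE")
})

test_that("binary association recovers planted phi and degenerate cases", {
  s <- data.frame(x = c(rep(TRUE, 5), rep(FALSE, 5)))
  s$y <- s$x
  expect_equal(binary_association(s, "x", "y")$phi, 1)

  co <- generate_cohort(cohort_params(n_genomes = 2000, cmd_tendamistat_phi = 0.3,
                                      seed = 23), tables = FALSE)
  r <- binary_association(co$truth, "has_cmd", "has_tendamistat")
  expect_lt(abs(r$phi - 0.3), 0.07)

  co0 <- generate_cohort(cohort_params(n_genomes = 2000, cmd_tendamistat_phi = 0,
                                       seed = 24), tables = FALSE)
  expect_lt(abs(binary_association(co0$truth, "has_cmd", "has_tendamistat")$phi), 0.1)
})

test_that("reference mapping is gap-aware", {
  aln <- as_alignment(data.frame(id = c("ref", "o"), residues = c("M-KT", "MAKT")))
  expect_equal(map_column_to_reference(aln, "ref", 3), 2)
  expect_true(is.na(map_column_to_reference(aln, "ref", 2)))
  for (j in 1:4) expect_equal(map_column_to_reference(aln, "o", j), j)
  expect_error(map_column_to_reference(aln, "nope", 1), "not in alignment")
})

test_that("enrichment scan: exact small-table cases and annotations", {
  # column 1: group A all 'N' (a=4), group B all 'H' (c=0) -> p = 1/C(10,4),
  # pseudocount fold; column 2: everyone 'H' -> p = 1, fold = 1
  recs <- data.frame(id = c(sprintf("a%d", 1:4), sprintf("b%d", 1:6)),
                     residues = c(rep("NH", 4), rep("HH", 6)))
  aln <- as_alignment(recs)
  groups <- setNames(c(rep("A", 4), rep("B", 6)), recs$id)
  res <- column_enrichment_scan(aln, groups, reference_id = "b1", min_count = 3)
  row_n <- res[res$residue == "N" & res$column == 1, ]
  expect_equal(row_n$p_raw, 1 / choose(10, 4), tolerance = 1e-12)
  expect_equal(row_n$fold_enrichment, (4.5 / 5) / (0.5 / 7), tolerance = 1e-12)
  expect_equal(row_n$label, "H1N")
  row_h <- res[res$residue == "H" & res$column == 2, ]
  expect_equal(row_h$p_raw, 1)
  expect_equal(row_h$fold_enrichment, 1)  # no pseudocount when c > 0
  expect_equal(row_h$label, "")

  # BH/Bonferroni are computed over the whole scan family jointly
  expect_equal(res$p_bh, benjamini_hochberg(res$p_raw), tolerance = 1e-12)
  expect_equal(res$p_bonferroni, bonferroni(res$p_raw), tolerance = 1e-12)
  expect_true(all(res$p_bonferroni >= res$p_raw))

  # label swap mirrors the table and leaves the two-sided p unchanged
  swapped <- setNames(ifelse(groups == "A", "B", "A"), names(groups))
  res_sw <- column_enrichment_scan(aln, swapped, reference_id = "b1", min_count = 3)
  rn <- res_sw[res_sw$residue == "N" & res_sw$column == 1, ]
  expect_equal(c(rn$a, rn$b, rn$c, rn$d), c(row_n$c, row_n$d, row_n$a, row_n$b))
  expect_equal(rn$p_raw, row_n$p_raw, tolerance = 1e-12)

  # sequence-order invariance
  perm <- c(7, 2, 9, 1, 10, 3, 8, 4, 6, 5)
  aln_p <- as_alignment(recs[perm, ])
  res_p <- column_enrichment_scan(aln_p, groups, reference_id = "b1", min_count = 3)
  key <- function(d) d[order(d$column, d$residue), c("a", "b", "c", "d", "p_raw")]
  expect_equal(key(res_p), key(res), ignore_attr = TRUE)

  expect_error(column_enrichment_scan(aln, groups, reference_id = "zz"), "not in alignment")
  expect_error(column_enrichment_scan(aln, setNames(rep("B", 10), recs$id)), "group A is empty")
})

test_that("gap policy controls the contingency margins", {
  recs <- data.frame(id = c("a1", "a2", "a3", "b1", "b2", "b3"),
                     residues = c("N", "N", "-", "H", "H", "-"))
  aln <- as_alignment(recs)
  groups <- setNames(c("A", "A", "A", "B", "B", "B"), recs$id)
  ex <- column_enrichment_scan(aln, groups, min_count = 2, gap_policy = "exclude")
  expect_equal(ex$a[ex$residue == "N"] + ex$b[ex$residue == "N"], 2)
  ab <- column_enrichment_scan(aln, groups, min_count = 2, gap_policy = "count_as_absent")
  expect_equal(ab$a[ab$residue == "N"] + ab$b[ab$residue == "N"], 3)
})

test_that("substitution census counts sequences and de-duplicates genomes", {
  # 9 group-A sequences over 7 genomes: 7 variant sequences in 6 genomes
  # (one genome holds two), mirroring a genome-level count one lower than
  # the sequence-level count; group B: 11 variant carriers in 11 genomes
  ids_a <- sprintf("qa%02d", 1:9)
  gen_a <- c("GA1", "GA1", "GA2", "GA3", "GA4", "GA5", "GA6", "GA7", "GA7")
  res_a <- c("N", "N", "N", "N", "N", "N", "H", "H", "N")  # 7 Ns over GA1,2,3,4,5,7
  ids_b <- sprintf("qb%02d", 1:20)
  gen_b <- sprintf("GB%02d", 1:20)
  res_b <- c(rep("N", 11), rep("H", 9))
  aln <- as_alignment(data.frame(id = c(ids_a, ids_b), residues = c(res_a, res_b)))
  groups <- setNames(c(rep("A", 9), rep("B", 20)), c(ids_a, ids_b))
  genome_of <- setNames(c(gen_a, gen_b), c(ids_a, ids_b))

  cen <- substitution_census(aln, groups, column = 1, wildtype_residue = "H",
                             variant_residues = "N", genome_of = genome_of,
                             level = "genome")
  expect_equal(unname(cen$sequence_counts), c(7, 11))
  expect_equal(unname(cen$genome_counts), c(6, 11))
  expect_equal(unname(unclass(cen$table)), c(6, 1, 11, 9))
  expect_equal(cen$p_value, fisher_exact(two_by_two(6, 1, 11, 9))$p_value)

  seq_cen <- substitution_census(aln, groups, 1, "H", "N", genome_of, level = "sequence")
  expect_equal(unname(unclass(seq_cen$table)), c(7, 2, 11, 9))

  # census levels differ only because GA1 holds two variant sequences
  expect_equal(cen$sequence_counts[["A"]] - cen$genome_counts[["A"]], 1)

  none <- substitution_census(aln, groups, 1, "H", "Q", genome_of, level = "sequence")
  expect_equal(unname(none$sequence_counts), c(0, 0))
  expect_equal(none$p_value, 1)

  expect_error(substitution_census(aln, groups, 1, "N", c("N", "A")), "wildtype")
})
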