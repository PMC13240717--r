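# Synthetic-data generators: determinism, planted structure, in-regime
# constraints, and validator compatibility.

test_that("cohort generation is deterministic and respects p_bgc = 0", {
  p <- cohort_params(n_genomes = 50, p_bgc = 0, amylase_count_shift_delta = 0, seed = 1)
  co <- generate_cohort(p)
  expect_false(any(co$truth$has_bgc))
  expect_false(any(grepl("gac", co$genes$roles)))
  expect_true(all(co$truth$total_amylases %in% 0:6))

  co2 <- generate_cohort(p)
  expect_identical(co, co2)

  co3 <- generate_cohort(cohort_params(n_genomes = 50, p_bgc = 0, seed = 2))
  expect_false(identical(co$truth$total_amylases, co3$truth$total_amylases))
})

test_that("planted count shift is recovered at large n", {
  p <- cohort_params(n_genomes = 2000, p_bgc = 0.05, amylase_count_shift_delta = 3, seed = 7)
  co <- generate_cohort(p, tables = FALSE)
  tr <- co$truth
  expect_gt(sum(tr$has_bgc), 0)
  diff_means <- mean(tr$total_amylases[tr$has_bgc]) - mean(tr$total_amylases[!tr$has_bgc])
  expect_lt(abs(diff_means - 3), 0.2)
  expect_true(all(tr$total_amylases <= 6))
})

test_that("cohort annotation tables are mutually consistent", {
  co <- generate_cohort(cohort_params(n_genomes = 25, p_bgc = 0.3, seed = 13))
  amy <- co$amylases
  # every amylase gene row has a GH13-recommended call, a secreted call and
  # clade-defining domains
  caz <- setNames(co$cazyme$recommended, co$cazyme$protein_id)
  expect_true(all(vapply(caz[amy$protein_id], is_recommended_gh13, logical(1))))
  sec <- setNames(toupper(co$secretion$call) != "OTHER", co$secretion$protein_id)
  expect_true(all(sec[amy$protein_id]))
  dom_by <- split(co$domains$domain, co$domains$protein_id)
  got_clades <- vapply(amy$protein_id, function(p) assign_clade(dom_by[[p]]), character(1))
  expect_equal(unname(got_clades), amy$clade)
  # BGC genomes carry a contiguous gac run
  for (g in co$truth$genome_id[co$truth$has_bgc]) {
    rows <- co$genes[co$genes$genome_id == g & grepl("gac", co$genes$roles), ]
    expect_equal(nrow(rows), 15)
    expect_equal(diff(range(rows$gene_index)), 14)
  }
  # impossible parameters are rejected
  expect_error(generate_cohort(cohort_params(n_genomes = 10, p_bgc = 0.5,
                                             amylase_count_shift_delta = 5,
                                             clamp_counts = FALSE, seed = 3)),
               "impossible")
  expect_error(cohort_params(cmd_tendamistat_phi = 2), "\\[-1, 1\\]")
})

test_that("MSA generator plants column substitutions as specified", {
  # freq_a = 1, freq_b = 0 separates the groups perfectly
  pl <- data.frame(column = 5, residue_a = "N", residue_b = "H", freq_a = 1, freq_b = 0)
  m <- generate_msa(msa_params(n_group_a = 10, n_group_b = 20, n_columns = 30,
                               planted_columns = pl, gap_probability = 0.1, seed = 4))
  chars <- substr(unname(m$alignment$seq), 5, 5)
  expect_true(all(chars[m$groups[m$alignment$id] == "A"] == "N"))
  expect_false(any(chars[m$groups[m$alignment$id] == "B"] %in% c("N", "H")))

  # no gaps anywhere when gap_probability = 0
  m0 <- generate_msa(msa_params(n_group_a = 5, n_group_b = 5, n_columns = 40,
                                gap_probability = 0, seed = 5,
                                planted_columns = pl))
  expect_false(any(grepl("-", m0$alignment$seq, fixed = TRUE)))

  # determinism
  p6 <- msa_params(n_group_a = 6, n_group_b = 6, n_columns = 25, seed = 6)
  expect_identical(generate_msa(p6), generate_msa(p6))

  # background columns are uniform: empirical frequencies within 3 sd of
  # the binomial expectation over 10,000 cells per residue class
  mb <- generate_msa(msa_params(n_group_a = 10, n_group_b = 10, n_columns = 500,
                                planted_columns = pl[0, ], gap_probability = 0, seed = 8))
  tab <- table(strsplit(paste(m_seqs <- unname(mb$alignment$seq), collapse = ""), "")[[1]])
  n_cells <- 20 * 500
  expected <- n_cells / 20
  sd3 <- 3 * sqrt(n_cells * (1 / 20) * (19 / 20))
  expect_length(tab, 20)
  expect_true(all(abs(tab - expected) <= sd3))

  expect_error(msa_params(planted_columns = data.frame(column = c(2, 2), residue_a = "A",
                                                       residue_b = "C", freq_a = .5, freq_b = .5)),
               "distinct")
})

test_that("random trees have the unrooted binary shape", {
  t3 <- generate_tree(3, seed = 1)
  expect_equal(ape::Ntip(t3), 3)
  expect_equal(t3$Nnode, 1)
  t100 <- generate_tree(100, seed = 2)
  expect_equal(nrow(t100$edge), 2 * 100 - 3)
  expect_false(ape::is.rooted(t100))
  expect_true(all(t100$edge.length >= 0))
  expect_identical(ape::write.tree(generate_tree(20, seed = 9)),
                   ape::write.tree(generate_tree(20, seed = 9)))
})

test_that("template alignment plants the resistance site in pullulanases", {
  co <- generate_cohort(cohort_params(n_genomes = 40, p_bgc = 0.25, seed = 17))
  msa <- build_amylase_alignment(co, mutation_rate = 0, p_resist_adjacent = 1,
                                 p_resist_background = 0, seed = 18)
  chars <- substr(unname(msa$alignment$seq), msa$resist_column, msa$resist_column)
  amy <- co$amylases
  pull <- amy$clade == "pullulanase"
  expect_true(all(chars[pull & amy$bgc_adjacent] == "N"))
  expect_true(all(chars[pull & !amy$bgc_adjacent] == "H"))
  # templates are equal length so the alignment is rectangular by construction
  expect_equal(msa$alignment$length, nchar(amylase_clade_templates()[[1]]))
})

test_that("generated fixtures pass every io validator", {
  d <- withr::local_tempdir()
  make_fixtures(d, seed = 42, n_genomes = 30)
  expect_silent({
    caz <- read_cazyme_table(file.path(d, "cazyme.tsv"))
    sec <- read_secretion_table(file.path(d, "secretion.tsv"))
    dom <- read_domain_table(file.path(d, "domains.tsv"))
    genes <- read_gene_table(file.path(d, "genes.tsv"))
    hmm <- read_hmm_hits(file.path(d, "hmm_hits.tsv"))
    aln <- read_alignment(file.path(d, "amylases.afa"))
    tree <- read_newick(file.path(d, "tree.nwk"))
  })
  expect_setequal(aln$id, tree$tip.label)
})
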