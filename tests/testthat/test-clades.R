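# Midpoint rooting, clade extraction, consensus and representative
# selection.

test_that("midpoint rooting balances the two deepest leaves", {
  # longest path B-C = 10; root must sit 5 from each
  tr <- read_newick(text = "((A:1,B:3):1,C:6);")
  rooted <- midpoint_root(tr)
  d <- root_to_leaf_depths(rooted)
  expect_equal(unname(d["B"]), 5, tolerance = 1e-9)
  expect_equal(unname(d["C"]), 5, tolerance = 1e-9)
  expect_equal(unname(d["A"]), 3, tolerance = 1e-9)

  # symmetric two-leaf tree
  tr2 <- read_newick(text = "(A:2,B:2);")
  d2 <- root_to_leaf_depths(midpoint_root(tr2))
  expect_equal(unname(d2), c(2, 2), tolerance = 1e-9)

  # property on random trees: max depth == diameter / 2, and invariance to
  # leaf order and to re-reading the written Newick
  for (s in 1:30) {
    tr <- generate_tree(sample(4:40, 1), seed = s)
    rooted <- midpoint_root(tr)
    dd <- root_to_leaf_depths(rooted)
    diam <- max(ape::cophenetic.phylo(tr))
    expect_equal(max(dd), diam / 2, tolerance = 1e-9)

    rot <- ape::rotateConstr(tr, rev(tr$tip.label))
    d_rot <- root_to_leaf_depths(midpoint_root(rot))
    expect_equal(d_rot[names(dd)], dd, tolerance = 1e-9)

    tmp <- withr::local_tempfile(fileext = ".nwk")
    write_newick(rooted, tmp)
    d_back <- root_to_leaf_depths(midpoint_root(read_newick(tmp)))
    expect_equal(d_back[names(dd)], dd, tolerance = 1e-7)
  }

  expect_error(midpoint_root(read_newick(text = "((A,B),C);")), "branch lengths")
  expect_error(midpoint_root(ape::read.tree(text = "(A:1);")), "two leaves")
})

test_that("greedy deepest-split clade extraction", {
  tr <- midpoint_root(read_newick(text = "((A:1,B:1):1,(C:1,D:1):1);"))
  expect_equal(partition_sets(extract_clades(tr, 1)), list(c("A", "B", "C", "D")))
  # balanced 4-leaf tree at k=2 gives the two cherries
  expect_setequal(partition_sets(extract_clades(tr, 2)), list(c("A", "B"), c("C", "D")))
  expect_error(extract_clades(tr, 5), "exceeds")

  # parameter recovery: three well-separated planted clades
  for (s in c(7, 8, 9)) {
    g <- generate_clade_tree(n_per_clade = c(6, 9, 12), seed = s)
    part <- extract_clades(midpoint_root(g$tree), 3)
    got <- partition_sets(part)
    want <- lapply(split(names(g$truth), g$truth), sort)
    expect_setequal(got, unname(want))
  }

  # clades are connected subtrees: each group's tips are exactly the
  # non-foreign tips under its LCA (nesting or disjointness with others)
  g <- generate_clade_tree(seed = 10)
  rooted <- midpoint_root(g$tree)
  part <- extract_clades(rooted, 4)
  sets <- partition_sets(part)
  for (i in seq_along(sets)) {
    mrca <- if (length(sets[[i]]) == 1) NULL else ape::getMRCA(rooted, sets[[i]])
    below <- if (is.null(mrca)) sets[[i]] else ape::extract.clade(rooted, mrca)$tip.label
    for (j in seq_along(sets)) {
      if (i == j) next
      overlap <- intersect(below, sets[[j]])
      expect_true(length(overlap) == 0 || setequal(overlap, sets[[j]]))
    }
  }
})

test_that("consensus sequence: majority, lexicographic ties, gap policies", {
  aln <- as_alignment(data.frame(
    id = c("s1", "s2", "s3"),
    residues = c("AAC-A", "ACC-A", "CCC-T")))
  expect_equal(consensus_sequence(aln), "ACC-A")
  # tie in column 1 of a two-member subset resolves lexicographically
  expect_equal(substr(consensus_sequence(aln, c("s1", "s3")), 1, 1), "A")
  expect_error(consensus_sequence(aln, character(0)), "empty")
  # all-gap column emits '-' under both policies
  expect_equal(substr(consensus_sequence(aln, gap_policy = "include_gaps"), 4, 4), "-")
})

test_that("representative selection maximizes identity to the consensus", {
  aln <- as_alignment(data.frame(
    id = c("far", "near", "exact"),
    residues = c("TTTTTTAAAA", "AAAAAATTAA", "AAAAAAAAAA")))
  # consensus is all A; 'exact' matches it fully
  expect_equal(select_representative(aln), "exact")
  expect_equal(select_representative(aln, c("far", "near")), "near")

  # brute-force oracle on random clade alignments
  withr::with_seed(55, {
    for (rep in 1:10) {
      n <- sample(5:20, 1); L <- sample(20:60, 1)
      recs <- data.frame(
        id = sprintf("m%02d", seq_len(n)),
        residues = vapply(seq_len(n), function(i) {
          paste(sample(c("A", "C", "D", "E", "-"), L, TRUE, prob = c(.4, .25, .15, .1, .1)),
                collapse = "")
        }, character(1)))
      aln_r <- as_alignment(recs)
      cons <- strsplit(consensus_sequence(aln_r), "", fixed = TRUE)[[1]]
      sims <- vapply(seq_len(n), function(i) {
        s <- strsplit(recs$residues[i], "", fixed = TRUE)[[1]]
        ok <- s != "-" & cons != "-"
        if (!any(ok)) 0 else mean(s[ok] == cons[ok])
      }, numeric(1))
      expect_equal(select_representative(aln_r), recs$id[which.max(sims)])
    }
  })

  # a sequence identical to the consensus always wins (up to earlier exact
  # matches, resolved by input order)
  cons <- consensus_sequence(aln)
  aug <- as_alignment(data.frame(id = c(aln$id, "clone"),
                                 residues = c(unname(aln$seq), cons)))
  expect_equal(select_representative(aug), "exact")  # earlier exact match keeps priority
  expect_equal(select_representative(aug, c("clone", "far", "near")), "clone")
})
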