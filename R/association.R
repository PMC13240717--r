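# Cohort-level association statistics and the MSA column-wise
# residue-enrichment scan.

#' Summarize a cohort into one row per genome
#'
#' Builds the genome-level table on which all cohort statistics run:
#' clade-wise and total amylase counts (genomes without amylases get
#' zeros), inhibitor-BGC flags, tendamistat presence and genome size.
#'
#' @param amylases Retained-amylase table ([filter_secreted_amylases()]
#'   `kept`, or [read_amylase_table()]); every `genome_id` must appear in
#'   `genome_metadata`.
#' @param bgc_flags Optional `data.frame` with `genome_id` and any of
#'   `has_acarbose_bgc`, `has_acarviostatin_bgc`, `has_trestatin_bgc`;
#'   genomes absent from it get `FALSE`.
#' @param tendamistat_flags Optional `data.frame` with `genome_id`,
#'   `has_tendamistat` ([filter_tendamistat_hits()]).
#' @param genome_metadata `data.frame` with `genome_id` and optionally
#'   `genome_size_bp`; defines the cohort universe.
#' @return A `data.frame` with one row per genome: counts per clade,
#'   `total_amylases`, `has_cmd`, BGC and tendamistat flags,
#'   `genome_size_bp`.
#' @export
summarize_cohort <- function(amylases, bgc_flags = NULL, tendamistat_flags = NULL,
                             genome_metadata) {
  stopifnot(is.data.frame(genome_metadata), "genome_id" %in% names(genome_metadata))
  gid <- genome_metadata$genome_id
  if (anyDuplicated(gid) > 0) stopf("duplicate genome_id in genome_metadata")
  if (nrow(amylases) > 0) {
    unknown <- setdiff(amylases$genome_id, gid)
    if (length(unknown) > 0) {
      stopf("amylase(s) reference unknown genome(s): %s", paste(unique(unknown), collapse = ", "))
    }
  }
  count_clade <- function(clade) {
    sub <- amylases[amylases$clade == clade, , drop = FALSE]
    as.integer(table(factor(sub$genome_id, levels = gid)))
  }
  out <- data.frame(genome_id = gid,
                    n_pullulanase = count_clade("pullulanase"),
                    n_alpha14 = count_clade("alpha14"),
                    n_cmd_like = count_clade("cmd_like"),
                    n_unassigned = count_clade("unassigned"),
                    stringsAsFactors = FALSE)
  out$total_amylases <- as.integer(table(factor(amylases$genome_id, levels = gid)))
  out$has_cmd <- out$n_cmd_like >= 1
  for (flag in c("has_acarbose_bgc", "has_acarviostatin_bgc", "has_trestatin_bgc")) {
    v <- rep(FALSE, length(gid))
    if (!is.null(bgc_flags) && flag %in% names(bgc_flags)) {
      i <- match(gid, bgc_flags$genome_id)
      v <- ifelse(is.na(i), FALSE, bgc_flags[[flag]][i])
    }
    out[[flag]] <- v
  }
  v <- rep(FALSE, length(gid))
  if (!is.null(tendamistat_flags)) {
    i <- match(gid, tendamistat_flags$genome_id)
    v <- ifelse(is.na(i), FALSE, tendamistat_flags$has_tendamistat[i])
  }
  out$has_tendamistat <- v
  out$genome_size_bp <- if ("genome_size_bp" %in% names(genome_metadata)) {
    genome_metadata$genome_size_bp
  } else NA_integer_
  out
}

#' Prevalence (percent of genomes) of a genome-level feature
#'
#' @param summaries A [summarize_cohort()] table.
#' @param count_field Name of a count column; prevalence is the percentage
#'   of genomes with a count of at least one (or a `TRUE` flag).
#' @return Percentage in `[0, 100]`.
#' @export
prevalence_pct <- function(summaries, count_field) {
  v <- summaries[[count_field]]
  if (is.null(v)) stopf("no column '%s' in summaries", count_field)
  100 * mean(if (is.logical(v)) v else v >= 1)
}

#' Rank-based association between a binary flag and a per-genome count
#'
#' Mann-Whitney U comparison of `count_field` between flagged and
#' unflagged genomes. The effect size is signed so that positive `r` means
#' flagged genomes have the larger counts.
#'
#' @param summaries A [summarize_cohort()] table.
#' @param flag_field Name of a logical column (e.g. `has_acarbose_bgc`).
#' @param count_field Name of a numeric column (e.g. `total_amylases`,
#'   `genome_size_bp`).
#' @param ... Passed to [mann_whitney_u()].
#' @return A [mann_whitney_u()] result list.
#' @export
count_association <- function(summaries, flag_field = "has_acarbose_bgc",
                              count_field = "total_amylases", ...) {
  flag <- summaries[[flag_field]]
  cnt <- summaries[[count_field]]
  if (is.null(flag) || is.null(cnt)) stopf("missing column '%s' or '%s'", flag_field, count_field)
  if (!any(flag)) stopf("group empty: no genome with %s = TRUE", flag_field)
  if (all(flag)) stopf("group empty: no genome with %s = FALSE", flag_field)
  mann_whitney_u(cnt[flag], cnt[!flag], ...)
}

#' Chi-square association between two binary genome-level flags
#'
#' @param summaries A [summarize_cohort()] table.
#' @param flag_a,flag_b Names of logical columns; `phi > 0` means the flags
#'   co-occur more often than expected.
#' @param ... Passed to [chi_square_2x2()].
#' @return A [chi_square_2x2()] result list.
#' @export
binary_association <- function(summaries, flag_a = "has_cmd",
                               flag_b = "has_tendamistat", ...) {
  a <- summaries[[flag_a]]; b <- summaries[[flag_b]]
  if (is.null(a) || is.null(b)) stopf("missing column '%s' or '%s'", flag_a, flag_b)
  if (anyNA(a) || anyNA(b)) stopf("binary_association: flags must be non-missing on every row")
  tab <- two_by_two(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b))
  chi_square_2x2(tab, ...)
}

#' Map an alignment column to an ungapped reference position
#'
#' @param alignment An `amy_alignment`.
#' @param reference_id Id of the reference sequence.
#' @param column 1-based alignment column.
#' @return The 1-based ungapped residue position in the reference, or `NA`
#'   when the reference is gapped at that column.
#' @export
map_column_to_reference <- function(alignment, reference_id, column) {
  if (!reference_id %in% alignment$id) stopf("reference id '%s' not in alignment", reference_id)
  if (column < 1 || column > alignment$length) stopf("column %d outside 1..%d", column, alignment$length)
  ref <- strsplit(unname(alignment$seq[reference_id]), "", fixed = TRUE)[[1]]
  if (ref[column] == "-") return(NA_integer_)
  sum(ref[seq_len(column)] != "-")
}

#' Column-wise residue-enrichment scan of a grouped alignment
#'
#' For every (column, residue) pair with total residue count of at least
#' `min_count`, tests whether the residue is differentially frequent
#' between group A (e.g. BGC-associated amylases) and group B with a
#' two-sided Fisher's exact test, corrects the whole scan jointly by
#' Benjamini-Hochberg and Bonferroni, and annotates each result with the
#' reference coordinate and a substitution label (e.g. `"H235G"`) where the
#' reference residue differs.
#'
#' Contingency cells: `a` = group-A members carrying the residue at the
#' column, `b` = group-A members without it, `c`/`d` likewise for group B.
#' Under the default `gap_policy = "exclude"`, members gapped at the column
#' are excluded from both margins; `"count_as_absent"` counts them in
#' `b`/`d`. Fold enrichment is `(a/nA) / (c/nB)` with row totals as
#' denominators; only when `c = 0` a Haldane-Anscombe 0.5 pseudocount is
#' added to every cell.
#'
#' @param alignment An `amy_alignment`.
#' @param group_labels Named vector over all alignment ids with values
#'   `"A"`/`"B"` (or a logical vector, `TRUE` = group A).
#' @param reference_id Id of the reference sequence used for coordinate
#'   mapping, or `NULL` to skip reference annotation.
#' @param min_count Minimum total residue count for a pair to be tested.
#' @param alpha Significance level recorded alongside the scan (used by the
#'   `significant` column on BH-adjusted p-values).
#' @param gap_policy `"exclude"` (default) or `"count_as_absent"`.
#' @return A `data.frame` sorted by raw p-value with columns `column`,
#'   `residue`, `a`, `b`, `c`, `d`, `fold_enrichment`, `p_raw`, `p_bh`,
#'   `p_bonferroni`, `significant`, `ref_position`, `label`.
#' @export
column_enrichment_scan <- function(alignment, group_labels, reference_id = NULL,
                                   min_count = 3, alpha = 0.05,
                                   gap_policy = c("exclude", "count_as_absent")) {
  gap_policy <- match.arg(gap_policy)
  if (is.logical(group_labels)) {
    group_labels <- stats::setNames(ifelse(group_labels, "A", "B"), names(group_labels))
  }
  missing <- setdiff(alignment$id, names(group_labels))
  if (length(missing) > 0) stopf("no group label for: %s", paste(missing, collapse = ", "))
  lab <- group_labels[alignment$id]
  if (!all(lab %in% c("A", "B"))) stopf("group labels must be 'A' or 'B'")
  if (!any(lab == "A")) stopf("group A is empty")
  if (!any(lab == "B")) stopf("group B is empty")
  if (!is.null(reference_id) && !reference_id %in% alignment$id) {
    stopf("reference id '%s' not in alignment", reference_id)
  }

  m <- alignment_matrix(alignment)
  ia <- which(lab == "A"); ib <- which(lab == "B")
  rows <- vector("list", alignment$length)
  for (j in seq_len(alignment$length)) {
    colA <- m[ia, j]; colB <- m[ib, j]
    nA_obs <- sum(colA != "-"); nB_obs <- sum(colB != "-")
    residues <- sort(unique(c(colA, colB)), method = "radix")
    residues <- residues[residues != "-"]
    if (length(residues) == 0) next
    counts_a <- vapply(residues, function(r) sum(colA == r), integer(1))
    counts_b <- vapply(residues, function(r) sum(colB == r), integer(1))
    keep <- (counts_a + counts_b) >= min_count
    if (!any(keep)) next
    residues <- residues[keep]; counts_a <- counts_a[keep]; counts_b <- counts_b[keep]
    na_j <- if (gap_policy == "exclude") nA_obs else length(ia)
    nb_j <- if (gap_policy == "exclude") nB_obs else length(ib)
    rows[[j]] <- data.frame(column = j, residue = residues,
                            a = counts_a, b = na_j - counts_a,
                            c = counts_b, d = nb_j - counts_b,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    return(data.frame(column = integer(0), residue = character(0), a = integer(0),
                      b = integer(0), c = integer(0), d = integer(0),
                      fold_enrichment = numeric(0), p_raw = numeric(0),
                      p_bh = numeric(0), p_bonferroni = numeric(0),
                      significant = logical(0), ref_position = integer(0),
                      label = character(0), stringsAsFactors = FALSE))
  }
  res$fold_enrichment <- fold_enrichment(res$a, res$b, res$c, res$d)
  res$p_raw <- vapply(seq_len(nrow(res)), function(i) {
    fisher_exact(c(res$a[i], res$b[i], res$c[i], res$d[i]))$p_value
  }, numeric(1))
  res$p_bh <- benjamini_hochberg(res$p_raw)
  res$p_bonferroni <- bonferroni(res$p_raw)
  res$significant <- res$p_bh < alpha

  if (!is.null(reference_id)) {
    ref <- strsplit(unname(alignment$seq[reference_id]), "", fixed = TRUE)[[1]]
    ref_pos_all <- cumsum(ref != "-")
    res$ref_position <- ifelse(ref[res$column] == "-", NA_integer_, ref_pos_all[res$column])
    ref_res <- ref[res$column]
    res$label <- ifelse(!is.na(res$ref_position) & ref_res != res$residue,
                        paste0(ref_res, res$ref_position, res$residue), "")
  } else {
    res$ref_position <- NA_integer_
    res$label <- ""
  }
  res <- res[order(res$p_raw, res$column, res$residue, method = "radix"), ]
  rownames(res) <- NULL
  res
}

# fold enrichment (a/nA)/(c/nB); Haldane-Anscombe +0.5 on all cells only
# when the group-B residue count is zero
fold_enrichment <- function(a, b, c, d) {
  na <- a + b; nb <- c + d
  out <- ifelse(c == 0,
                ((a + 0.5) / (na + 1)) / ((c + 0.5) / (nb + 1)),
                (a / na) / (c / nb))
  # a zero group-A margin (all-gap column in A) is degenerate; report NaN
  out[na == 0] <- NaN
  out
}

#' Census of a substitution at one alignment column
#'
#' Counts, per group, the sequences carrying any of the variant residues at
#' the column, de-duplicates to genome level when a genome mapping is
#' given, and tests group enrichment of the variant with a two-sided
#' Fisher's exact test at the chosen level.
#'
#' @inheritParams column_enrichment_scan
#' @param column 1-based alignment column of the site.
#' @param wildtype_residue The reference residue (must not be among
#'   `variant_residues`).
#' @param variant_residues Non-empty character vector of variant residues.
#' @param genome_of Optional named vector mapping sequence ids to genome
#'   ids (required for `level = "genome"`).
#' @param level `"sequence"` or `"genome"`: the unit of the contingency
#'   table.
#' @return A list with `sequence_counts` and `genome_counts` (per-group
#'   variant carriers; genome counts `NA` without a mapping), `table`
#'   (the [two_by_two()] at `level`), `fold_enrichment`, `p_value` and
#'   `level`.
#' @export
substitution_census <- function(alignment, group_labels, column,
                                wildtype_residue, variant_residues,
                                genome_of = NULL,
                                level = c("sequence", "genome")) {
  level <- match.arg(level)
  if (length(variant_residues) == 0) stopf("variant_residues must be non-empty")
  if (wildtype_residue %in% variant_residues) {
    stopf("wildtype residue '%s' cannot also be a variant", wildtype_residue)
  }
  if (column < 1 || column > alignment$length) stopf("column %d outside 1..%d", column, alignment$length)
  if (is.logical(group_labels)) {
    group_labels <- stats::setNames(ifelse(group_labels, "A", "B"), names(group_labels))
  }
  lab <- group_labels[alignment$id]
  if (anyNA(lab) || !all(lab %in% c("A", "B"))) stopf("group labels must cover all ids with 'A'/'B'")
  if (level == "genome" && is.null(genome_of)) stopf("genome-level census needs a genome_of mapping")

  chars <- substr(unname(alignment$seq), column, column)
  carrier <- chars %in% variant_residues
  seq_counts <- c(A = sum(carrier & lab == "A"), B = sum(carrier & lab == "B"))
  seq_totals <- c(A = sum(lab == "A"), B = sum(lab == "B"))

  genome_counts <- c(A = NA_integer_, B = NA_integer_)
  genome_totals <- NULL
  if (!is.null(genome_of)) {
    gmap <- genome_of[alignment$id]
    if (anyNA(gmap)) stopf("genome_of must map every sequence id")
    # a genome counts for group A if it has any group-A sequence
    g_group <- vapply(split(lab, gmap), function(l) if (any(l == "A")) "A" else "B", character(1))
    g_carrier <- vapply(split(carrier, gmap), any, logical(1))
    genome_counts <- c(A = sum(g_carrier & g_group == "A"), B = sum(g_carrier & g_group == "B"))
    genome_totals <- c(A = sum(g_group == "A"), B = sum(g_group == "B"))
  }

  counts <- if (level == "sequence") seq_counts else genome_counts
  totals <- if (level == "sequence") seq_totals else genome_totals
  tab <- two_by_two(counts[["A"]], totals[["A"]] - counts[["A"]],
                    counts[["B"]], totals[["B"]] - counts[["B"]])
  list(sequence_counts = seq_counts, genome_counts = genome_counts,
       table = tab,
       fold_enrichment = fold_enrichment(tab[["a"]], tab[["b"]], tab[["c"]], tab[["d"]]),
       p_value = fisher_exact(tab)$p_value,
       level = level)
}
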