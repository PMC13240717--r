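# Seeded generators for cohorts, annotation tables, MSAs and trees with
# known planted structure, so every downstream stage has a
# parameter-recovery test without any external data.
#
# All randomness flows from the single `seed` field of the parameter
# object; the session RNG state is saved and restored around generation.

STD_AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
            "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

GAC_ROLES <- paste0("gac", c("A", "V", "W", "X", "Y", "U", "S", "R", "K",
                             "I", "Q", "C", "J", "M", "O"))

CLADE_LEVELS <- c("pullulanase", "alpha14", "cmd_like")

#' Parameters of a synthetic genome cohort
#'
#' Defaults emulate the regime of a genus-wide survey: 295 genomes, ~5%
#' carrying an amylase-inhibitor BGC, per-genome secreted-amylase counts
#' confined to 0-6, a +3 count shift in BGC-carrying genomes, clade mix
#' dominated by pullulanases and alpha-1,4-amylases, ~13% tendamistat
#' prevalence with a planted phi = 0.16 association to
#' cyclomaltodextrin-like amylase presence, and 8.5 +/- 0.4 Mb genomes.
#' The base count distribution lives on {0..3} so the +3 shift stays inside
#' the observed 0-6 range without clamping distortion.
#'
#' @param n_genomes Number of genomes.
#' @param p_bgc Probability a genome carries an inhibitor BGC.
#' @param amylase_count_base Named probability vector over counts (names
#'   are integers within 0..6).
#' @param amylase_count_shift_delta Non-negative integer added to the
#'   amylase count of BGC-carrying genomes.
#' @param clade_mix Probabilities over clades
#'   (`pullulanase`, `alpha14`, `cmd_like`); must sum to 1.
#' @param p_tendamistat Marginal probability of a tendamistat-like gene.
#' @param cmd_tendamistat_phi Planted phi association between
#'   cyclomaltodextrin-like amylase presence and tendamistat presence.
#' @param genome_size_mean,genome_size_sd Genome size distribution (bp).
#' @param clamp_counts Clamp shifted counts into 0..6 (default); with
#'   clamping disabled, a shift pushing any count above 6 is an error.
#' @param seed Integer seed; the single source of randomness.
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(n_genomes = 295,
                          p_bgc = 0.05,
                          amylase_count_base = c("0" = 0.10, "1" = 0.35, "2" = 0.35, "3" = 0.20),
                          amylase_count_shift_delta = 3,
                          clade_mix = c(pullulanase = 0.45, alpha14 = 0.45, cmd_like = 0.10),
                          p_tendamistat = 0.13,
                          cmd_tendamistat_phi = 0.16,
                          genome_size_mean = 8.5e6,
                          genome_size_sd = 4e5,
                          clamp_counts = TRUE,
                          seed = 1) {
  stopifnot(n_genomes >= 1, p_bgc >= 0, p_bgc < 1,
            p_tendamistat > 0, p_tendamistat < 1,
            amylase_count_shift_delta >= 0,
            amylase_count_shift_delta == floor(amylase_count_shift_delta),
            genome_size_mean > 0, genome_size_sd >= 0)
  if (abs(sum(amylase_count_base) - 1) > 1e-8) stopf("amylase_count_base must sum to 1")
  counts <- suppressWarnings(as.integer(names(amylase_count_base)))
  if (anyNA(counts) || any(counts < 0 | counts > 6)) {
    stopf("amylase_count_base names must be integer counts within 0..6")
  }
  if (is.null(names(clade_mix)) || !setequal(names(clade_mix), CLADE_LEVELS)) {
    stopf("clade_mix must be named with %s", paste(CLADE_LEVELS, collapse = ", "))
  }
  if (abs(sum(clade_mix) - 1) > 1e-8) stopf("clade_mix must sum to 1")
  if (abs(cmd_tendamistat_phi) > 1) stopf("cmd_tendamistat_phi must be in [-1, 1]")
  structure(list(n_genomes = as.integer(n_genomes), p_bgc = p_bgc,
                 amylase_count_base = amylase_count_base,
                 amylase_count_shift_delta = as.integer(amylase_count_shift_delta),
                 clade_mix = clade_mix[CLADE_LEVELS],
                 p_tendamistat = p_tendamistat,
                 cmd_tendamistat_phi = cmd_tendamistat_phi,
                 genome_size_mean = genome_size_mean, genome_size_sd = genome_size_sd,
                 clamp_counts = isTRUE(clamp_counts), seed = as.integer(seed)),
            class = "cohort_params")
}

# conditional tendamistat probabilities achieving the planted phi given the
# realized cmd-presence margin
tendamistat_probs <- function(px, pt, phi) {
  if (px <= 0 || px >= 1 || phi == 0) return(c(p1 = pt, p0 = pt))
  p11 <- px * pt + phi * sqrt(px * (1 - px) * pt * (1 - pt))
  p1 <- p11 / px
  p0 <- (pt - p11) / (1 - px)
  if (p1 < 0 || p1 > 1 || p0 < 0 || p0 > 1) {
    stopf("impossible params: planted phi = %.3g incompatible with margins (p_cmd = %.3g, p_tendamistat = %.3g)",
          phi, px, pt)
  }
  c(p1 = p1, p0 = p0)
}

#' Generate a synthetic genome cohort
#'
#' Draws per-genome inhibitor-BGC carriage, clade-typed amylase counts
#' (shifted upward in BGC carriers), tendamistat presence with the planted
#' association to cyclomaltodextrin-like amylase presence, and genome
#' sizes. With `tables = TRUE` (default) it also materializes mutually
#' consistent annotation tables: an ordered gene table in which BGC
#' carriers receive a contiguous run of the 15 aminocyclitol core genes
#' with a planted number (1-4, capped by the genome's amylase count) of
#' immediately adjacent amylase genes; CAZyme, secretion and
#' conserved-domain tables in which every amylase gene is GH13-recommended,
#' secreted and carries its clade-defining domains; per-genome decoy
#' proteins exercising each filter stage (a GH13 protein without a
#' secretion signal, a secreted GH13 protein without amylase domains, and a
#' secreted non-GH13 protein); and a tendamistat HMM-hit table with
#' sub-cutoff hits in tendamistat-positive genomes plus occasional
#' above-cutoff decoy hits.
#'
#' @param params A [cohort_params()] object.
#' @param tables Materialize the annotation tables (set `FALSE` for fast
#'   cohort-level simulations that only need `truth`).
#' @return A list with `truth` (per-genome ground-truth data frame),
#'   `amylases` (per-amylase ground truth: protein, genome, clade,
#'   BGC-adjacency), and when `tables = TRUE` also `genes`, `cazyme`,
#'   `secretion`, `domains`, `hmm_hits`, `genomes` (metadata table); plus
#'   the `params` used.
#' @export
generate_cohort <- function(params, tables = TRUE) {
  stopifnot(inherits(params, "cohort_params"))
  withr::with_seed(params$seed, generate_cohort_impl(params, tables))
}

generate_cohort_impl <- function(params, tables) {
  n <- params$n_genomes
  gid <- sprintf("G%04d", seq_len(n))
  has_bgc <- stats::runif(n) < params$p_bgc
  base_vals <- as.integer(names(params$amylase_count_base))
  counts <- sample(base_vals, n, replace = TRUE, prob = params$amylase_count_base)
  counts <- counts + params$amylase_count_shift_delta * has_bgc
  if (any(counts > 6)) {
    if (!params$clamp_counts) {
      stopf("impossible params: shifted amylase count exceeds 6 with clamping disabled")
    }
    counts <- pmin(counts, 6L)
  }
  clade_counts <- t(vapply(counts, function(k) {
    if (k == 0) c(0L, 0L, 0L) else as.integer(stats::rmultinom(1, k, params$clade_mix))
  }, integer(3)))
  colnames(clade_counts) <- CLADE_LEVELS
  has_cmd <- clade_counts[, "cmd_like"] >= 1
  pr <- tendamistat_probs(mean(has_cmd), params$p_tendamistat, params$cmd_tendamistat_phi)
  has_tend <- stats::runif(n) < ifelse(has_cmd, pr[["p1"]], pr[["p0"]])
  gsize <- pmax(1e6, round(stats::rnorm(n, params$genome_size_mean, params$genome_size_sd)))
  planted_flanking <- ifelse(has_bgc, pmin(counts, sample(1:4, n, replace = TRUE)), 0L)

  truth <- data.frame(genome_id = gid, has_bgc = has_bgc,
                      has_tendamistat = has_tend, has_cmd = has_cmd,
                      n_pullulanase = clade_counts[, "pullulanase"],
                      n_alpha14 = clade_counts[, "alpha14"],
                      n_cmd_like = clade_counts[, "cmd_like"],
                      total_amylases = as.integer(counts),
                      planted_flanking = as.integer(planted_flanking),
                      genome_size_bp = as.integer(gsize),
                      stringsAsFactors = FALSE)

  out <- list(truth = truth, params = params)
  if (!tables) return(out)

  gene_rows <- vector("list", n)
  caz_rows <- vector("list", n)
  sec_rows <- vector("list", n)
  dom_rows <- vector("list", n)
  hmm_rows <- vector("list", n)
  amy_rows <- vector("list", n)

  for (i in seq_len(n)) {
    g <- build_genome_tables(gid[i], has_bgc[i], clade_counts[i, ],
                             planted_flanking[i], has_tend[i])
    gene_rows[[i]] <- g$genes; caz_rows[[i]] <- g$cazyme; sec_rows[[i]] <- g$secretion
    dom_rows[[i]] <- g$domains; hmm_rows[[i]] <- g$hmm; amy_rows[[i]] <- g$amylases
  }
  out$genes <- do.call(rbind, gene_rows)
  out$cazyme <- do.call(rbind, caz_rows)
  out$secretion <- do.call(rbind, sec_rows)
  out$domains <- do.call(rbind, dom_rows)
  hmm <- do.call(rbind, hmm_rows)
  out$hmm_hits <- if (is.null(hmm)) {
    data.frame(protein_id = character(0), genome_id = character(0),
               e_value = numeric(0), score = numeric(0), stringsAsFactors = FALSE)
  } else hmm
  out$amylases <- do.call(rbind, amy_rows) %||%
    data.frame(protein_id = character(0), genome_id = character(0),
               clade = character(0), bgc_adjacent = logical(0), stringsAsFactors = FALSE)
  out$genomes <- data.frame(genome_id = gid, genome_size_bp = truth$genome_size_bp,
                            stringsAsFactors = FALSE)
  rownames(out$genes) <- rownames(out$cazyme) <- rownames(out$secretion) <- NULL
  rownames(out$domains) <- rownames(out$hmm_hits) <- rownames(out$amylases) <- NULL
  out
}

CLADE_DOMAINS <- list(
  pullulanase = data.frame(domain = c("pullul_strch", "AmyAc_bac_euk_AmyA", "PUD"),
                           start = c(420L, 60L, 340L), end = c(780L, 330L, 410L)),
  alpha14 = data.frame(domain = c("AmyAc_bac_euk_AmyA", "CBM20"),
                       start = c(45L, 400L), end = c(380L, 490L)),
  cmd_like = data.frame(domain = c("AmyAc_bac_CMD_like_2", "Aamy_C"),
                        start = c(35L, 390L), end = c(360L, 470L))
)

# one synthetic genome: ordered gene layout plus consistent annotations.
# Layout (single contig): 8 leading fillers | [gac run + adjacent amylases]
# | 18 spacer fillers | remaining amylases each preceded by 2 fillers |
# 8 trailing fillers. Spacing keeps the planted cluster away from contig
# edges and from non-adjacent amylases at the default neighborhood
# parameters.
build_genome_tables <- function(gid, has_bgc, clade_counts, flanking, has_tend) {
  total <- sum(clade_counts)
  clades <- rep(CLADE_LEVELS, clade_counts)
  if (length(clades) > 1) clades <- sample(clades)
  n_adj <- if (has_bgc) flanking else 0L
  roles <- c(rep("", 8),
             if (has_bgc) GAC_ROLES,
             if (n_adj > 0) rep("amylase", n_adj),
             rep("", 18),
             unlist(lapply(seq_len(max(0, total - n_adj)), function(i) c("", "", "amylase"))),
             rep("", 8))
  ng <- length(roles)
  pid <- sprintf("%s_p%03d", gid, seq_len(ng))
  genes <- data.frame(genome_id = gid, contig_id = "c1",
                      gene_index = seq(0L, ng - 1L), protein_id = pid,
                      roles = roles,
                      at_contig_edge = seq_len(ng) %in% c(1L, ng),
                      stringsAsFactors = FALSE)

  amy_pid <- pid[roles == "amylase"]
  adj_flag <- rep(FALSE, length(amy_pid))
  if (n_adj > 0) adj_flag[seq_len(n_adj)] <- TRUE  # adjacent block comes first

  amylases <- if (length(amy_pid) > 0) {
    data.frame(protein_id = amy_pid, genome_id = gid, clade = clades,
               bgc_adjacent = adj_flag, stringsAsFactors = FALSE)
  } else NULL

  # decoys: one per filter stage, drawn from filler genes
  fillers <- pid[roles == ""]
  decoy <- fillers[1:3]
  rec_choices <- c("GH13", "GH13_32", "GH13;CBM20")
  amy_rec <- if (length(amy_pid) > 0) sample(rec_choices, length(amy_pid), replace = TRUE) else character(0)

  cazyme <- data.frame(
    protein_id = c(amy_pid, decoy),
    hmmer = c(amy_rec, "GH13", "GH13_28", "GH31"),
    diamond = c(rep("GH13", length(amy_pid)), "GH13", "GH13_28", "GH31"),
    recommended = c(amy_rec, "GH13", "GH13_28", "GH31"),
    stringsAsFactors = FALSE)

  secretion <- data.frame(
    protein_id = c(amy_pid, decoy),
    call = c(rep("SP", length(amy_pid)), "OTHER", "SP", "SP"),
    probability = round(c(stats::runif(length(amy_pid), 0.9, 1), stats::runif(1, 0, 0.1),
                          stats::runif(2, 0.9, 1)), 4),
    stringsAsFactors = FALSE)

  dom_list <- lapply(seq_along(amy_pid), function(j) {
    d <- CLADE_DOMAINS[[clades[j]]]
    data.frame(protein_id = amy_pid[j], domain = d$domain, start = d$start, end = d$end,
               e_value = signif(10^stats::runif(nrow(d), -40, -15), 4),
               stringsAsFactors = FALSE)
  })
  dom_list[[length(dom_list) + 1]] <- data.frame(
    protein_id = decoy[2], domain = "FN3", start = 10L, end = 100L,
    e_value = signif(10^stats::runif(1, -20, -10), 4), stringsAsFactors = FALSE)
  domains <- do.call(rbind, dom_list)

  hmm <- NULL
  if (has_tend) {
    hmm <- data.frame(protein_id = paste0(gid, "_tend1"), genome_id = gid,
                      e_value = signif(10^stats::runif(1, -30, -12), 4),
                      score = round(stats::runif(1, 80, 250), 1),
                      stringsAsFactors = FALSE)
  } else if (stats::runif(1) < 0.15) {
    # weak decoy hit above the default cutoff
    hmm <- data.frame(protein_id = decoy[3], genome_id = gid,
                      e_value = signif(10^stats::runif(1, -9, -4), 4),
                      score = round(stats::runif(1, 10, 40), 1),
                      stringsAsFactors = FALSE)
  }

  list(genes = genes, cazyme = cazyme, secretion = secretion,
       domains = domains, hmm = hmm, amylases = amylases)
}

#' Parameters of a synthetic grouped MSA
#'
#' Defaults mirror the cohort regime used throughout the package's
#' simulations: 15 group-A (BGC-associated) and 285 group-B sequences, 400
#' columns, five planted columns at which group A carries its residue with
#' frequency 0.6 and group B carries a different residue with frequency
#' 0.04, a uniform background over the 20 standard amino acids, and 2%
#' gaps.
#'
#' At a planted column the fallback background excludes both planted
#' residues (so `freq_a = 1, freq_b = 0` yields perfect group separation,
#' and the planted frequencies are exact); planted columns receive no gaps.
#'
#' @param n_group_a,n_group_b Group sizes.
#' @param n_columns Alignment length.
#' @param planted_columns `data.frame` with columns `column`, `residue_a`,
#'   `residue_b`, `freq_a`, `freq_b`; columns must be distinct and within
#'   range. `NULL` plants the default five columns.
#' @param background_alphabet_frequencies Named probability vector over
#'   residues (default uniform over the 20 standard amino acids).
#' @param gap_probability Per-cell gap probability in `[0, 1)` applied to
#'   non-planted columns.
#' @param seed Integer seed.
#' @return A list of class `msa_params`.
#' @export
msa_params <- function(n_group_a = 15, n_group_b = 285, n_columns = 400,
                       planted_columns = NULL,
                       background_alphabet_frequencies = NULL,
                       gap_probability = 0.02, seed = 1) {
  stopifnot(n_group_a >= 1, n_group_b >= 1, n_columns >= 1,
            gap_probability >= 0, gap_probability < 1)
  if (is.null(planted_columns)) {
    planted_columns <- data.frame(
      column = round(seq(0.1, 0.9, length.out = 5) * n_columns),
      residue_a = c("N", "G", "T", "W", "K"),
      residue_b = c("H", "H", "D", "R", "E"),
      freq_a = 0.6, freq_b = 0.04, stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(planted_columns),
            all(c("column", "residue_a", "residue_b", "freq_a", "freq_b") %in% names(planted_columns)))
  if (anyDuplicated(planted_columns$column) > 0) stopf("planted columns must be distinct")
  if (any(planted_columns$column < 1 | planted_columns$column > n_columns)) {
    stopf("planted column outside 1..n_columns")
  }
  if (any(planted_columns$freq_a < 0 | planted_columns$freq_a > 1 |
          planted_columns$freq_b < 0 | planted_columns$freq_b > 1)) {
    stopf("planted frequencies must be in [0, 1]")
  }
  bg <- background_alphabet_frequencies %||%
    stats::setNames(rep(1 / length(STD_AA), length(STD_AA)), STD_AA)
  if (abs(sum(bg) - 1) > 1e-8) stopf("background frequencies must sum to 1")
  structure(list(n_group_a = as.integer(n_group_a), n_group_b = as.integer(n_group_b),
                 n_columns = as.integer(n_columns), planted_columns = planted_columns,
                 background = bg, gap_probability = gap_probability,
                 seed = as.integer(seed)),
            class = "msa_params")
}

#' Generate a grouped MSA with planted column substitutions
#'
#' @param params An [msa_params()] object.
#' @return A list with `alignment` (an `amy_alignment`, ids `A###`/`B###`)
#'   and `groups` (named character vector of `"A"`/`"B"` labels).
#' @export
generate_msa <- function(params) {
  stopifnot(inherits(params, "msa_params"))
  withr::with_seed(params$seed, generate_msa_impl(params))
}

generate_msa_impl <- function(params) {
  na <- params$n_group_a; nb <- params$n_group_b; nc <- params$n_columns
  n <- na + nb
  aa <- names(params$background)
  m <- matrix(sample(aa, n * nc, replace = TRUE, prob = params$background), n, nc)
  if (params$gap_probability > 0) {
    m[stats::runif(n * nc) < params$gap_probability] <- "-"
  }
  ia <- seq_len(na); ib <- na + seq_len(nb)
  for (r in seq_len(nrow(params$planted_columns))) {
    pc <- params$planted_columns[r, ]
    excl <- unique(c(pc$residue_a, pc$residue_b))
    bg2 <- params$background[setdiff(aa, excl)]
    bg2 <- bg2 / sum(bg2)
    fa <- stats::runif(na) < pc$freq_a
    m[ia, pc$column] <- ifelse(fa, pc$residue_a,
                               sample(names(bg2), na, replace = TRUE, prob = bg2))
    fb <- stats::runif(nb) < pc$freq_b
    m[ib, pc$column] <- ifelse(fb, pc$residue_b,
                               sample(names(bg2), nb, replace = TRUE, prob = bg2))
  }
  ids <- c(sprintf("A%03d", seq_len(na)), sprintf("B%03d", seq_len(nb)))
  aln <- as_alignment(data.frame(id = ids, description = "",
                                 residues = apply(m, 1, paste, collapse = ""),
                                 stringsAsFactors = FALSE))
  groups <- stats::setNames(c(rep("A", na), rep("B", nb)), ids)
  list(alignment = aln, groups = groups)
}

#' Generate a random unrooted bifurcating tree
#'
#' Random topology with exponentially distributed branch lengths.
#'
#' @param n_leaves Number of leaves (>= 3 for an unrooted binary tree; 2
#'   gives the trivial two-leaf tree).
#' @param seed Integer seed.
#' @param rate Rate of the exponential branch-length distribution.
#' @return An unrooted `phylo` object with leaf labels `t1..tn`.
#' @export
generate_tree <- function(n_leaves, seed = 1, rate = 1) {
  stopifnot(n_leaves >= 2)
  withr::with_seed(as.integer(seed), {
    ape::rtree(n_leaves, rooted = FALSE, br = function(k) stats::rexp(k, rate))
  })
}

#' Generate a tree with three well-separated planted clades
#'
#' Three random subtrees with short internal branches joined by long
#' separating branches, giving a recoverable ground-truth 3-clade
#' partition.
#'
#' @param n_per_clade Integer vector of clade sizes (length 3).
#' @param separation Length of each clade-separating branch; with the
#'   default within-clade branch rate this is ~10x the within-clade span.
#' @param within_rate Exponential rate of within-clade branch lengths.
#' @param seed Integer seed.
#' @return A list with `tree` (unrooted `phylo`, tips `c<i>_t<j>`) and
#'   `truth` (named integer vector, tip -> clade 1..3).
#' @export
generate_clade_tree <- function(n_per_clade = c(8, 8, 8), separation = 10,
                                within_rate = 5, seed = 1) {
  stopifnot(length(n_per_clade) == 3, all(n_per_clade >= 2))
  withr::with_seed(as.integer(seed), {
    parts <- lapply(1:3, function(i) {
      tr <- ape::rtree(n_per_clade[i], rooted = TRUE,
                       br = function(k) stats::rexp(k, within_rate))
      tr$tip.label <- sprintf("c%d_t%02d", i, seq_len(n_per_clade[i]))
      sub(";$", "", ape::write.tree(tr))
    })
    txt <- sprintf("(%s:%g,%s:%g,%s:%g);", parts[[1]], separation,
                   parts[[2]], separation, parts[[3]], separation)
    tree <- ape::read.tree(text = txt)
    truth <- stats::setNames(as.integer(sub("^c(\\d+)_.*$", "\\1", tree$tip.label)),
                             tree$tip.label)
    list(tree = tree, truth = truth)
  })
}

#' Fixed clade template sequences
#'
#' Three equal-length amino-acid templates, one per amylase clade, sharing
#' a common catalytic core but differing in clade-diagnostic stretches.
#' Position 60 carries the catalytic histidine whose substitution by
#' asparagine marks inhibitor resistance in the synthetic model. These are
#' synthetic fixtures, not real protein accessions.
#'
#' @return Named character vector of length 3 (`pullulanase`, `alpha14`,
#'   `cmd_like`), each 120 residues.
#' @export
amylase_clade_templates <- function() {
  core1 <- "MKRLTAVALSAGLLFSGAAQAADNGTVIVHLFEWKWDDIA"  # 40
  core2 <- "AEFGSKADLVRGMGFDAVWHSMNADGYGSYDLIPSVENQA"  # 40, catalytic H at overall column 60
  c(pullulanase = paste0(core1, core2, "YDLGEFQQKGTVRTKYGTKAELQDAIGSLHSRGVKVYADV"),
    alpha14     = paste0(core1, core2, "WTNEMIRGSVDNWADRGIDGFRIDAAKHMPFGWQKSWVSS"),
    cmd_like    = paste0(core1, core2, "NHDTDIGWLRQGNSEAYKDQAVLSYAFMLTSPGIPCIFYG"))
}

#' Build a template-derived alignment for a cohort's amylases
#'
#' Each amylase sequence is its clade template with independent point
#' substitutions (no indels, so the sequences are trivially aligned). At
#' the resistance site (template column 60, histidine), pullulanase-clade
#' amylases adjacent to a planted BGC carry asparagine with probability
#' `p_resist_adjacent`, other pullulanases with probability
#' `p_resist_background`; other clades keep their template residue.
#'
#' @param cohort A [generate_cohort()] result with tables.
#' @param mutation_rate Per-site substitution probability.
#' @param p_resist_adjacent,p_resist_background Asparagine probabilities at
#'   the resistance site.
#' @param resist_column Template column of the resistance site.
#' @param seed Integer seed.
#' @return A list with `alignment`, `groups` (named `"A"`/`"B"`: BGC-adjacent
#'   or not) and `resist_column`.
#' @export
build_amylase_alignment <- function(cohort, mutation_rate = 0.02,
                                    p_resist_adjacent = 0.9,
                                    p_resist_background = 0.04,
                                    resist_column = 60, seed = 1) {
  amy <- cohort$amylases
  if (is.null(amy) || nrow(amy) == 0) stopf("cohort contains no amylases")
  tmpl <- lapply(amylase_clade_templates(), function(s) strsplit(s, "", fixed = TRUE)[[1]])
  len <- length(tmpl[[1]])
  withr::with_seed(as.integer(seed), {
    seqs <- vapply(seq_len(nrow(amy)), function(i) {
      s <- tmpl[[amy$clade[i]]]
      mut <- stats::runif(len) < mutation_rate
      if (any(mut)) s[mut] <- sample(STD_AA, sum(mut), replace = TRUE)
      if (amy$clade[i] == "pullulanase") {
        p <- if (amy$bgc_adjacent[i]) p_resist_adjacent else p_resist_background
        s[resist_column] <- if (stats::runif(1) < p) "N" else "H"
      }
      paste(s, collapse = "")
    }, character(1))
    aln <- as_alignment(data.frame(id = amy$protein_id, description = "",
                                   residues = seqs, stringsAsFactors = FALSE))
    groups <- stats::setNames(ifelse(amy$bgc_adjacent, "A", "B"), amy$protein_id)
    list(alignment = aln, groups = groups, resist_column = resist_column)
  })
}
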