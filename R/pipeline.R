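# End-to-end orchestration: mine -> clades -> bgc -> associate -> scan,
# plus fixture materialization. The pipeline is a pure function of
# (inputs, config, seed): reruns produce byte-identical TSVs.

#' Analysis configuration
#'
#' Collects every tunable parameter of the pipeline with its default:
#' significance level `alpha = 0.05`, HMM E-value cutoff `1e-10`, `k = 3`
#' tree clades, the cluster queries (acarbose-like by default), gene-window
#' neighborhood parameters, gap policy and minimum count of the enrichment
#' scan, and the census level.
#'
#' @param input_dir Directory containing the pipeline inputs
#'   (`cazyme.tsv`, `secretion.tsv`, `domains.tsv`, `genes.tsv`,
#'   `hmm_hits.tsv`, `genomes.tsv`, `amylases.afa`, `tree.nwk`).
#' @param output_dir Directory for the report bundle (created if needed).
#' @param alpha Significance cutoff in `(0, 1)`.
#' @param hmm_evalue_cutoff E-value cutoff for tendamistat hits.
#' @param k_clades Number of tree clades to extract.
#' @param queries List of [bgc_query()] objects.
#' @param max_gene_gap,flank_genes,required_fraction Neighborhood
#'   parameters (see [bgc_query()], [count_flanking_amylases()]).
#' @param gap_policy,min_count Enrichment-scan parameters
#'   ([column_enrichment_scan()]).
#' @param census_level `"sequence"` or `"genome"`
#'   ([substitution_census()]).
#' @param reference_id Reference sequence for coordinate mapping; `NULL`
#'   selects the representative of clade 1.
#' @param seed Integer seed recorded in the manifest.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(input_dir, output_dir,
                            alpha = 0.05, hmm_evalue_cutoff = 1e-10,
                            k_clades = 3, queries = NULL,
                            max_gene_gap = 5, flank_genes = 10,
                            required_fraction = 1.0,
                            gap_policy = "exclude", min_count = 3,
                            census_level = "genome",
                            reference_id = NULL, seed = 1) {
  stopifnot(alpha > 0, alpha < 1, hmm_evalue_cutoff > 0, k_clades >= 1)
  queries <- queries %||% list(acarbose_query(max_gene_gap = max_gene_gap,
                                              required_fraction = required_fraction))
  structure(list(input_dir = input_dir, output_dir = output_dir, alpha = alpha,
                 hmm_evalue_cutoff = hmm_evalue_cutoff, k_clades = as.integer(k_clades),
                 queries = queries, max_gene_gap = as.integer(max_gene_gap),
                 flank_genes = as.integer(flank_genes),
                 required_fraction = required_fraction, gap_policy = gap_policy,
                 min_count = as.integer(min_count), census_level = census_level,
                 reference_id = reference_id, seed = as.integer(seed)),
            class = "analysis_config")
}

stage_try <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })
}

#' Run the full mining-and-association pipeline
#'
#' Executes the stages in order (mine, clades, bgc, associate, scan) on the
#' input directory and writes the report bundle: `amylases.tsv`,
#' `clades.tsv`, `representatives.tsv`, `bgc_loci.tsv`,
#' `genome_flags.tsv`, `genome_summaries.tsv`, `association_stats.tsv`,
#' `enrichment.tsv`, `run_log.txt` and a machine-readable `manifest.json`
#' (package version, configuration, configuration hash, seed, stage
#' record counts). Statistical tests that cannot run (e.g. an empty
#' comparison group) are reported as structured failures in
#' `association_stats.tsv` rather than aborting, so earlier outputs are
#' always written; any other stage error aborts with the stage name.
#'
#' @param config An [analysis_config()].
#' @return Invisibly, a list with the output paths, the stage log, the
#'   genome summaries and the association table.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  ind <- config$input_dir
  outd <- config$output_dir
  dir.create(outd, showWarnings = FALSE, recursive = TRUE)
  logline <- character(0)
  note <- function(...) logline <<- c(logline, sprintf(...))

  # ---- mine ----
  mine <- stage_try("mine", {
    cazyme <- read_cazyme_table(file.path(ind, "cazyme.tsv"))
    secretion <- read_secretion_table(file.path(ind, "secretion.tsv"))
    domains <- read_domain_table(file.path(ind, "domains.tsv"))
    genes <- read_gene_table(file.path(ind, "genes.tsv"))
    res <- filter_secreted_amylases(cazyme, secretion, domains, genes = genes)
    note("mine: %d proteins annotated", nrow(cazyme))
    note("mine: %d GH13-recommended", nrow(res$kept) + length(res$dropped_no_signal) +
           length(res$dropped_no_domain))
    note("mine: %d dropped (no secretion signal)", length(res$dropped_no_signal))
    note("mine: %d dropped (no amylase/pullulanase domain)", length(res$dropped_no_domain))
    note("mine: %d secreted amylases kept", nrow(res$kept))
    list(res = res, genes = genes)
  })
  write_amylase_table(mine$res$kept, file.path(outd, "amylases.tsv"))

  # ---- clades ----
  clades <- stage_try("clades", {
    aln <- read_alignment(file.path(ind, "amylases.afa"))
    tree <- read_newick(file.path(ind, "tree.nwk"))
    if (!setequal(tree$tip.label, aln$id)) {
      stopf("tree leaves and alignment ids differ")
    }
    rooted <- midpoint_root(tree)
    part <- extract_clades(rooted, config$k_clades)
    reps <- vapply(seq_len(part$k), function(i) {
      select_representative(aln, names(part$assignments)[part$assignments == i])
    }, character(1))
    note("clades: %d leaves cut into %d clades (sizes %s)", length(part$assignments),
         part$k, paste(tabulate(part$assignments, part$k), collapse = "/"))
    list(aln = aln, part = part, reps = reps)
  })
  write_tsv(data.frame(protein_id = names(clades$part$assignments),
                       clade_index = unname(clades$part$assignments),
                       stringsAsFactors = FALSE),
            file.path(outd, "clades.tsv"))
  write_tsv(data.frame(clade_index = seq_along(clades$reps),
                       representative = clades$reps, stringsAsFactors = FALSE),
            file.path(outd, "representatives.tsv"))

  # ---- bgc ----
  bgc <- stage_try("bgc", {
    genomes <- read_table_checked(file.path(ind, "genomes.tsv"),
                                  c("genome_id", "genome_size_bp"), "genomes")
    genomes$genome_size_bp <- as_int_col(genomes$genome_size_bp, "genome_size_bp", "genomes")
    hmm <- read_hmm_hits(file.path(ind, "hmm_hits.tsv"))
    loci <- do.call(rbind, lapply(config$queries, function(q) find_bgc_loci(mine$genes, q)))
    loci$flanking_amylase_count <- vapply(seq_len(nrow(loci)), function(i) {
      count_flanking_amylases(loci[i, ], mine$genes, config$flank_genes)
    }, integer(1))
    flags <- data.frame(genome_id = genomes$genome_id, stringsAsFactors = FALSE)
    for (q in config$queries) {
      flags[[paste0("has_", q$name, "_bgc")]] <-
        genomes$genome_id %in% loci$genome_id[loci$name == q$name]
    }
    tend <- filter_tendamistat_hits(hmm, config$hmm_evalue_cutoff, genomes$genome_id)
    note("bgc: %d loci detected across %d genomes", nrow(loci), length(unique(loci$genome_id)))
    note("bgc: %d genomes with tendamistat-like hits at E <= %g",
         sum(tend$has_tendamistat), config$hmm_evalue_cutoff)
    list(genomes = genomes, loci = loci, flags = flags, tend = tend)
  })
  write_tsv(bgc$loci, file.path(outd, "bgc_loci.tsv"))
  flags_out <- merge(bgc$flags, bgc$tend, by = "genome_id", sort = TRUE)
  write_tsv(flags_out, file.path(outd, "genome_flags.tsv"))

  # ---- associate ----
  assoc <- stage_try("associate", {
    summaries <- summarize_cohort(mine$res$kept, bgc$flags, bgc$tend, bgc$genomes)
    flag_cols <- setdiff(names(bgc$flags), "genome_id")
    tests <- list()
    add_count_test <- function(name, flag, count) {
      row <- tryCatch({
        r <- count_association(summaries, flag, count)
        data.frame(test = name, type = "mann_whitney", statistic = r$u_statistic,
                   p_value = r$p_value, effect = r$effect_size_r, effect_type = "rank_biserial_r",
                   n_true = r$n_x, n_false = r$n_y, status = "ok", stringsAsFactors = FALSE)
      }, error = function(e) {
        data.frame(test = name, type = "mann_whitney", statistic = NA_real_,
                   p_value = NA_real_, effect = NA_real_, effect_type = "rank_biserial_r",
                   n_true = NA_integer_, n_false = NA_integer_,
                   status = paste0("failed: ", conditionMessage(e)), stringsAsFactors = FALSE)
      })
      tests[[length(tests) + 1]] <<- row
    }
    for (fc in flag_cols) {
      add_count_test(paste0("amylase_count~", fc), fc, "total_amylases")
      add_count_test(paste0("genome_size~", fc), fc, "genome_size_bp")
    }
    add_count_test("amylase_count~has_tendamistat", "has_tendamistat", "total_amylases")
    add_count_test("genome_size~has_tendamistat", "has_tendamistat", "genome_size_bp")
    bin <- tryCatch({
      r <- binary_association(summaries, "has_cmd", "has_tendamistat")
      data.frame(test = "cmd_presence~has_tendamistat", type = "chi_square",
                 statistic = r$chi2, p_value = r$p_value, effect = r$phi,
                 effect_type = "phi", n_true = sum(summaries$has_cmd),
                 n_false = sum(!summaries$has_cmd), status = "ok", stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(test = "cmd_presence~has_tendamistat", type = "chi_square",
                 statistic = NA_real_, p_value = NA_real_, effect = NA_real_,
                 effect_type = "phi", n_true = NA_integer_, n_false = NA_integer_,
                 status = paste0("failed: ", conditionMessage(e)), stringsAsFactors = FALSE)
    })
    tests[[length(tests) + 1]] <- bin
    stats_df <- do.call(rbind, tests)
    n_failed <- sum(stats_df$status != "ok")
    note("associate: %d tests run, %d structured failure(s)", nrow(stats_df), n_failed)
    list(summaries = summaries, stats = stats_df)
  })
  write_tsv(assoc$summaries, file.path(outd, "genome_summaries.tsv"))
  write_tsv(assoc$stats, file.path(outd, "association_stats.tsv"))

  # ---- scan ----
  scan <- stage_try("scan", {
    # group A: amylases within the flanked neighborhood of any detected locus
    adj <- rep(FALSE, nrow(mine$res$kept))
    if (nrow(bgc$loci) > 0 && nrow(mine$res$kept) > 0) {
      for (i in seq_len(nrow(bgc$loci))) {
        l <- bgc$loci[i, ]
        adj <- adj | (mine$res$kept$genome_id == l$genome_id &
                        mine$res$kept$contig_id == l$contig_id &
                        !is.na(mine$res$kept$gene_index) &
                        mine$res$kept$gene_index >= l$span_start - config$flank_genes &
                        mine$res$kept$gene_index <= l$span_end + config$flank_genes)
      }
    }
    labels <- stats::setNames(ifelse(adj, "A", "B"), mine$res$kept$protein_id)
    labels <- labels[names(labels) %in% clades$aln$id]
    ref <- config$reference_id %||% clades$reps[1]
    if (!any(labels == "A") || !any(labels == "B")) {
      note("scan: skipped (one neighborhood group empty)")
      res <- data.frame(column = integer(0), residue = character(0), a = integer(0),
                        b = integer(0), c = integer(0), d = integer(0),
                        fold_enrichment = numeric(0), p_raw = numeric(0),
                        p_bh = numeric(0), p_bonferroni = numeric(0),
                        significant = logical(0), ref_position = integer(0),
                        label = character(0), stringsAsFactors = FALSE)
    } else {
      res <- column_enrichment_scan(clades$aln, labels, reference_id = ref,
                                    min_count = config$min_count, alpha = config$alpha,
                                    gap_policy = config$gap_policy)
      note("scan: %d (column, residue) pairs tested, %d significant at BH < %g",
           nrow(res), sum(res$significant), config$alpha)
    }
    res
  })
  write_tsv(scan, file.path(outd, "enrichment.tsv"))

  # ---- manifest ----
  cfg <- unclass(config)
  cfg$queries <- lapply(cfg$queries, unclass)
  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, null = "null")
  manifest <- list(package = "amylatlas",
                   version = as.character(utils::packageVersion("amylatlas")),
                   seed = config$seed,
                   config = cfg,
                   config_hash = fnv1a_hex(as.character(cfg_json)),
                   stage_log = logline)
  jsonlite::write_json(manifest, file.path(outd, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  writeLines(logline, file.path(outd, "run_log.txt"))

  invisible(list(output_dir = outd, log = logline, summaries = assoc$summaries,
                 association_stats = assoc$stats, enrichment = scan,
                 loci = bgc$loci, partition = clades$part,
                 representatives = clades$reps))
}

#' Materialize a synthetic fixture cohort
#'
#' Writes a small synthetic cohort (annotation tables, template-derived
#' amylase alignment and a random tree over the amylase ids, genome
#' metadata and ground-truth tables) into a directory in exactly the
#' formats [run_pipeline()] consumes. Generation advances deterministically
#' through derived sub-seeds until the sampled cohort contains at least two
#' BGC-carrying, two non-carrying and two tendamistat-positive genomes, so
#' every pipeline stage is exercised for any seed; the same `seed` always
#' reproduces a byte-identical directory.
#'
#' @param dir Output directory.
#' @param seed Integer seed.
#' @param n_genomes Cohort size (kept small; the fixture exists to exercise
#'   stages, not to estimate anything precisely).
#' @param p_bgc BGC carriage probability used for the fixture cohort.
#' @return Invisibly, the [generate_cohort()] result that was written.
#' @export
make_fixtures <- function(dir, seed = 42, n_genomes = 60, p_bgc = 0.12) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- NULL
  for (try_seed in as.integer(seed) + 1000L * (0:19)) {
    cand <- generate_cohort(cohort_params(n_genomes = n_genomes, p_bgc = p_bgc,
                                          seed = try_seed))
    ok <- sum(cand$truth$has_bgc) >= 2 && sum(!cand$truth$has_bgc) >= 2 &&
      sum(cand$truth$has_tendamistat) >= 2 && nrow(cand$amylases) >= 4
    if (ok) { cohort <- cand; break }
  }
  if (is.null(cohort)) stopf("could not realize a stage-complete fixture cohort from seed %d", seed)

  write_cazyme_table(cohort$cazyme, file.path(dir, "cazyme.tsv"))
  write_secretion_table(cohort$secretion, file.path(dir, "secretion.tsv"))
  write_domain_table(cohort$domains, file.path(dir, "domains.tsv"))
  write_gene_table(cohort$genes, file.path(dir, "genes.tsv"))
  write_hmm_hits(cohort$hmm_hits, file.path(dir, "hmm_hits.tsv"))
  write_tsv(cohort$genomes, file.path(dir, "genomes.tsv"))
  write_tsv(cohort$truth, file.path(dir, "truth_genomes.tsv"))
  write_tsv(cohort$amylases, file.path(dir, "truth_amylases.tsv"))

  msa <- build_amylase_alignment(cohort, seed = cohort$params$seed + 1L)
  write_alignment(msa$alignment, file.path(dir, "amylases.afa"))
  tree <- generate_tree(nrow(cohort$amylases), seed = cohort$params$seed + 2L)
  tree$tip.label <- cohort$amylases$protein_id
  write_newick(tree, file.path(dir, "tree.nwk"))
  invisible(cohort)
}
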