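# Required/optional-gene cluster detection over ordered gene tables, with
# flanking-amylase counting and tendamistat HMM-hit filtering. Windows are
# measured in genes, not base pairs, and strand is ignored: the gene model
# is ordinal, which is the deliberate simplification behind the synthetic
# cohort generator.

#' Define a cluster query
#'
#' @param name Query name (e.g. `"acarbose"`).
#' @param required_genes Non-empty character vector of required role labels
#'   (the aminocyclitol core genes for acarbose-like clusters).
#' @param optional_genes Character vector of optional role labels; matches
#'   extend a locus but are not required.
#' @param max_gene_gap Maximum number of consecutive non-matching genes
#'   allowed between matches within one locus.
#' @param required_fraction Minimum fraction of `required_genes` a locus
#'   must contain, in `(0, 1]`.
#' @return A list of class `bgc_query`.
#' @export
bgc_query <- function(name, required_genes, optional_genes = character(0),
                      max_gene_gap = 5, required_fraction = 1.0) {
  if (length(required_genes) == 0) stopf("required_genes must be non-empty")
  stopifnot(max_gene_gap >= 0, required_fraction > 0, required_fraction <= 1)
  structure(list(name = name, required_genes = unique(required_genes),
                 optional_genes = unique(optional_genes),
                 max_gene_gap = as.integer(max_gene_gap),
                 required_fraction = required_fraction),
            class = "bgc_query")
}

#' The default acarbose-like cluster query
#'
#' Required genes are the 15 aminocyclitol-synthesis core genes
#' gac(A, V, W, X, Y, U, S, R, K, I, Q, C, J, M, O); amylases and
#' tendamistat-like genes are optional neighbours.
#'
#' @inheritParams bgc_query
#' @return A [bgc_query()].
#' @export
acarbose_query <- function(max_gene_gap = 5, required_fraction = 1.0) {
  bgc_query("acarbose", GAC_ROLES, c("amylase", "tendamistat_like"),
            max_gene_gap = max_gene_gap, required_fraction = required_fraction)
}

#' Detect cluster loci in an ordered gene table
#'
#' Scans each contig for maximal runs of genes matching the query's
#' required or optional roles, where consecutive matches are separated by
#' at most `max_gene_gap` non-matching genes, and keeps runs containing at
#' least `required_fraction` of the required genes. A locus whose span
#' comes within `max_gene_gap` genes of a contig end is flagged as
#' potentially truncated.
#'
#' @param gene_table Ordered gene table ([read_gene_table()]); rows must be
#'   sorted by contig and ascending `gene_index` within each
#'   (genome, contig).
#' @param query A [bgc_query()].
#' @return A `data.frame` of loci: `genome_id`, `contig_id`, `name`,
#'   `span_start`, `span_end` (gene indices), `n_required`,
#'   `matched_required`, `matched_optional` (`;`-joined),
#'   `truncated_at_contig_edge`.
#' @export
find_bgc_loci <- function(gene_table, query) {
  stopifnot(inherits(query, "bgc_query"), is.data.frame(gene_table))
  validate_gene_table(gene_table)
  keys <- paste(gene_table$genome_id, gene_table$contig_id, sep = "\r")
  for (k in unique(keys)) {
    idx <- gene_table$gene_index[keys == k]
    if (is.unsorted(idx, strictly = TRUE)) {
      stopf("gene table not sorted by gene_index within contig of genome '%s'", sub("\r.*", "", k))
    }
  }
  roles <- split_set(gene_table$roles)
  targets <- c(query$required_genes, query$optional_genes)
  is_match <- vapply(roles, function(r) length(intersect(r, targets)) > 0, logical(1))

  loci <- list()
  for (k in unique(keys)) {
    sel <- which(keys == k)
    hit <- sel[is_match[sel]]
    if (length(hit) == 0) next
    idx <- gene_table$gene_index[hit]
    run_id <- cumsum(c(1, diff(idx) > query$max_gene_gap + 1))
    contig_min <- min(gene_table$gene_index[sel])
    contig_max <- max(gene_table$gene_index[sel])
    for (rid in unique(run_id)) {
      rows <- hit[run_id == rid]
      run_roles <- unique(unlist(roles[rows]))
      matched_req <- intersect(query$required_genes, run_roles)
      if (length(matched_req) < query$required_fraction * length(query$required_genes)) next
      span <- range(gene_table$gene_index[rows])
      loci[[length(loci) + 1]] <- data.frame(
        genome_id = gene_table$genome_id[rows[1]],
        contig_id = gene_table$contig_id[rows[1]],
        name = query$name,
        span_start = span[1], span_end = span[2],
        n_required = length(matched_req),
        matched_required = join_set(list(sort(matched_req))),
        matched_optional = join_set(list(sort(intersect(query$optional_genes, run_roles)))),
        truncated_at_contig_edge = (span[1] - contig_min) <= query$max_gene_gap ||
          (contig_max - span[2]) <= query$max_gene_gap,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, loci) %||% data.frame(
    genome_id = character(0), contig_id = character(0), name = character(0),
    span_start = integer(0), span_end = integer(0), n_required = integer(0),
    matched_required = character(0), matched_optional = character(0),
    truncated_at_contig_edge = logical(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Count amylase genes in and around a locus
#'
#' Number of genes with role `"amylase"` whose index lies within the locus
#' span or within `flank_genes` positions of either span end, clipped at
#' contig boundaries.
#'
#' @param locus One row of a [find_bgc_loci()] table (or a list with
#'   `genome_id`, `contig_id`, `span_start`, `span_end`).
#' @param gene_table The gene table the locus came from.
#' @param flank_genes Flank width in genes on each side.
#' @return Integer count.
#' @export
count_flanking_amylases <- function(locus, gene_table, flank_genes = 10) {
  stopifnot(flank_genes >= 0)
  sel <- gene_table$genome_id == locus$genome_id &
    gene_table$contig_id == locus$contig_id &
    gene_table$gene_index >= locus$span_start - flank_genes &
    gene_table$gene_index <= locus$span_end + flank_genes
  sum(vapply(split_set(gene_table$roles[sel]), function(r) "amylase" %in% r, logical(1)))
}

#' Per-genome tendamistat flags from HMM hits
#'
#' A genome is flagged when it has at least one hit with E-value at or
#' below the cutoff (default 1e-10).
#'
#' @param hits HMM hit table ([read_hmm_hits()]); E-values must be
#'   strictly positive.
#' @param cutoff E-value cutoff.
#' @param genomes Optional character vector of the cohort's genome ids, so
#'   genomes without any hit appear with `FALSE`.
#' @return A `data.frame` with `genome_id`, `has_tendamistat`.
#' @export
filter_tendamistat_hits <- function(hits, cutoff = 1e-10, genomes = NULL) {
  stopifnot(is.data.frame(hits), cutoff > 0)
  if (nrow(hits) > 0 && (anyNA(hits$e_value) || any(hits$e_value <= 0))) {
    stopf("hmm hits: E-values must be strictly positive")
  }
  universe <- sort(unique(c(genomes %||% character(0), hits$genome_id)))
  flagged <- unique(hits$genome_id[hits$e_value <= cutoff])
  data.frame(genome_id = universe, has_tendamistat = universe %in% flagged,
             stringsAsFactors = FALSE)
}
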