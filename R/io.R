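# Readers/writers for every external format the pipeline touches.
# Canonical tabular dialect: TSV with a header row; set-valued cells are
# ';'-separated. Residue and MSA coordinates are 1-based inclusive throughout.

AA_CHARS <- "A-Z\\*"

#' Read a protein FASTA file
#'
#' Parses a (possibly gzipped) FASTA file into a data frame of sequence
#' records. Identifiers are the first whitespace-delimited token of each
#' header; the remainder is kept as the description. Residues must be
#' uppercase amino-acid letters (`*` permitted); alignment gaps (`-`) are
#' only accepted by [read_alignment()].
#'
#' @param path Path to a FASTA file.
#' @param allow_gaps Permit `-` characters (used internally by
#'   [read_alignment()]).
#' @return A `data.frame` with columns `id`, `description`, `residues`.
#' @seealso [write_fasta()], [read_alignment()]
#' @export
read_fasta <- function(path, allow_gaps = FALSE) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stopf("malformed FASTA '%s': %s", path, conditionMessage(e)))
  if (length(set) == 0) stopf("empty FASTA file: %s", path)
  nm <- names(set) %||% rep("", length(set))
  id <- sub("\\s.*$", "", nm)
  desc <- ifelse(grepl("\\s", nm), sub("^\\S+\\s+", "", nm), "")
  if (any(id == "")) stopf("FASTA record with empty id in %s", path)
  dup <- unique(id[duplicated(id)])
  if (length(dup) > 0) stopf("duplicate sequence id(s): %s", paste(dup, collapse = ", "))
  residues <- as.character(set)
  pat <- if (allow_gaps) sprintf("^[%s-]+$", AA_CHARS) else sprintf("^[%s]+$", AA_CHARS)
  bad <- id[!grepl(pat, residues)]
  if (length(bad) > 0) {
    stopf("invalid residues (need uppercase amino-acid letters%s) in: %s",
          if (allow_gaps) " or '-'" else "", paste(bad, collapse = ", "))
  }
  data.frame(id = id, description = desc, residues = residues, stringsAsFactors = FALSE)
}

#' Write sequence records to FASTA
#'
#' @param records A `data.frame` with columns `id`, `residues` and optionally
#'   `description`, as returned by [read_fasta()].
#' @param path Output path.
#' @param width Line-wrapping width.
#' @return The path, invisibly.
#' @export
write_fasta <- function(records, path, width = 60) {
  stopifnot(is.data.frame(records), all(c("id", "residues") %in% names(records)))
  desc <- if ("description" %in% names(records)) records$description else rep("", nrow(records))
  hdr <- ifelse(desc == "" | is.na(desc), records$id, paste(records$id, desc))
  set <- Biostrings::BStringSet(stats::setNames(records$residues, hdr))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Construct an alignment object from sequence records
#'
#' @param records A `data.frame` with `id`, `residues` (and optionally
#'   `description`) of identical residue-string lengths.
#' @return An object of class `amy_alignment` with fields `id`,
#'   `description`, `seq` and `length` (number of columns).
#' @export
as_alignment <- function(records) {
  stopifnot(is.data.frame(records), all(c("id", "residues") %in% names(records)))
  if (nrow(records) == 0) stopf("alignment must contain at least one sequence")
  lens <- nchar(records$residues)
  if (length(unique(lens)) != 1) {
    ref <- lens[1]  # first record sets the expected width
    stopf("ragged alignment: sequences with length != %d: %s",
          ref, paste(records$id[lens != ref], collapse = ", "))
  }
  structure(list(id = records$id,
                 description = if ("description" %in% names(records)) records$description else rep("", nrow(records)),
                 seq = stats::setNames(records$residues, records$id),
                 length = lens[1]),
            class = "amy_alignment")
}

#' Read an aligned FASTA file
#'
#' Like [read_fasta()] but permits `-` gap characters and enforces equal
#' sequence lengths, naming any offending ids.
#'
#' @inheritParams read_fasta
#' @return An `amy_alignment` object (see [as_alignment()]).
#' @export
read_alignment <- function(path) {
  as_alignment(read_fasta(path, allow_gaps = TRUE))
}

#' Write an alignment to aligned FASTA
#' @param alignment An `amy_alignment`.
#' @param path Output path.
#' @param width Line-wrapping width.
#' @export
write_alignment <- function(alignment, path, width = 60) {
  stopifnot(inherits(alignment, "amy_alignment"))
  write_fasta(data.frame(id = alignment$id, description = alignment$description,
                         residues = unname(alignment$seq), stringsAsFactors = FALSE),
              path, width = width)
}

#' @export
print.amy_alignment <- function(x, ...) {
  cat(sprintf("amy_alignment: %d sequences x %d columns\n", length(x$id), x$length))
  invisible(x)
}

# character matrix view (rows = sequences, named by id)
alignment_matrix <- function(alignment, ids = NULL) {
  stopifnot(inherits(alignment, "amy_alignment"))
  ids <- ids %||% alignment$id
  missing <- setdiff(ids, alignment$id)
  if (length(missing) > 0) stopf("ids not in alignment: %s", paste(missing, collapse = ", "))
  m <- do.call(rbind, strsplit(unname(alignment$seq[ids]), "", fixed = TRUE))
  rownames(m) <- ids
  m
}

#' Read a Newick tree
#'
#' Parses a single Newick tree. Internal node labels (bootstrap support
#' strings of any flavour) are stored verbatim and never interpreted as
#' numbers. Unbalanced parentheses are reported with their character
#' position.
#'
#' @param path Path to a Newick file, or a literal Newick string when `text`
#'   is used.
#' @param text Optional literal Newick string (overrides `path`).
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  txt <- if (!is.null(text)) text else {
    if (!file.exists(path)) stopf("Newick file not found: %s", path)
    paste(readLines(path, warn = FALSE), collapse = "")
  }
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  depth <- 0
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1
    if (chars[i] == ")") depth <- depth - 1
    if (depth < 0) stopf("Newick parse error: unbalanced ')' at position %d", i)
  }
  if (depth != 0) stopf("Newick parse error: %d unclosed '(' at end of input", depth)
  tr <- tryCatch(suppressWarnings(ape::read.tree(text = txt)),
                 error = function(e) stopf("Newick parse error: %s", conditionMessage(e)))
  if (is.null(tr)) stopf("Newick parse error: could not parse tree")
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1) stopf("expected a single Newick tree, found %d", length(tr))
    tr <- tr[[1]]
  }
  dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
  if (length(dup) > 0) stopf("duplicate leaf labels: %s", paste(dup, collapse = ", "))
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0, na.rm = TRUE)) {
    stopf("negative branch lengths are not allowed")
  }
  tr
}

#' Write a tree to Newick
#' @param tree A `phylo` object.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path, digits = 15)
  invisible(path)
}

# ---- tabular dialects -------------------------------------------------------

read_table_checked <- function(path, required, table_name) {
  if (!file.exists(path)) stopf("%s table not found: %s", table_name, path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    stopf("%s table '%s': missing mandatory column(s): %s",
          table_name, path, paste(miss, collapse = ", "))
  }
  extra <- setdiff(names(df), required)
  if (length(extra) > 0) {
    warning(sprintf("%s table '%s': ignoring unknown column(s): %s",
                    table_name, path, paste(extra, collapse = ", ")), call. = FALSE)
  }
  df[required]
}

as_num_col <- function(x, col, table_name, positive = FALSE) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !(is.na(x) | x == ""))
  if (length(bad) > 0) stopf("%s: non-numeric value '%s' in column '%s'", table_name, x[bad[1]], col)
  if (positive && any(v <= 0, na.rm = TRUE)) {
    stopf("%s: column '%s' must be > 0 (found %s)", table_name, col, v[which(v <= 0)[1]])
  }
  v
}

as_int_col <- function(x, col, table_name) {
  v <- as_num_col(x, col, table_name)
  if (any(v != floor(v), na.rm = TRUE)) stopf("%s: non-integer value in column '%s'", table_name, col)
  as.integer(v)
}

as_logical_col <- function(x, col, table_name) {
  v <- rep(NA, length(x))
  v[toupper(x) %in% c("TRUE", "T", "1")] <- TRUE
  v[toupper(x) %in% c("FALSE", "F", "0")] <- FALSE
  if (anyNA(v)) stopf("%s: non-logical value '%s' in column '%s'", table_name, x[which(is.na(v))[1]], col)
  v
}

FAMILY_PATTERN <- "^[A-Za-z]+[0-9]+(_[0-9]+)?$"

validate_families <- function(fams, table_name) {
  flat <- unlist(fams)
  bad <- flat[!grepl(FAMILY_PATTERN, flat)]
  if (length(bad) > 0) {
    stopf("%s: malformed CAZyme family string(s): %s", table_name, paste(unique(bad), collapse = ", "))
  }
  invisible(fams)
}

#' Read a CAZyme annotation table
#'
#' Merged-overview style TSV with columns `protein_id`, `hmmer`, `diamond`,
#' `recommended`; family calls within a cell are `;`-separated (empty or `-`
#' means no call). Family strings must match `FAMILY` or `FAMILY_SUBFAM`
#' (e.g. `GH13`, `GH13_32`, `CBM20`).
#'
#' @param path Path to a TSV file.
#' @return A `data.frame` with character columns `protein_id`, `hmmer`,
#'   `diamond`, `recommended` (sets kept `;`-joined).
#' @export
read_cazyme_table <- function(path) {
  df <- read_table_checked(path, c("protein_id", "hmmer", "diamond", "recommended"), "cazyme")
  dup <- unique(df$protein_id[duplicated(df$protein_id)])
  if (length(dup) > 0) stopf("cazyme: duplicate protein_id(s): %s", paste(dup, collapse = ", "))
  for (col in c("hmmer", "diamond", "recommended")) validate_families(split_set(df[[col]]), "cazyme")
  df
}

#' Read a secretion-call table
#'
#' TSV with columns `protein_id`, `call`, `probability`. A protein is
#' considered secreted when `call` is any signal-peptide class (anything
#' other than `OTHER`, `NONE` or empty), mirroring signal-peptide predictor
#' output classes.
#'
#' @param path Path to a TSV file.
#' @return A `data.frame` with `protein_id`, `call`, `is_secreted`,
#'   `probability`.
#' @export
read_secretion_table <- function(path) {
  df <- read_table_checked(path, c("protein_id", "call", "probability"), "secretion")
  prob <- as_num_col(df$probability, "probability", "secretion")
  if (any(prob < 0 | prob > 1, na.rm = TRUE)) stopf("secretion: probability outside [0,1]")
  data.frame(protein_id = df$protein_id, call = df$call,
             is_secreted = !(toupper(df$call) %in% c("OTHER", "NONE", "")),
             probability = prob, stringsAsFactors = FALSE)
}

#' Read a conserved-domain hit table
#'
#' TSV with columns `protein_id`, `domain`, `start`, `end`, `e_value`;
#' coordinates are 1-based inclusive residue positions.
#'
#' @param path Path to a TSV file.
#' @return A typed `data.frame`.
#' @export
read_domain_table <- function(path) {
  df <- read_table_checked(path, c("protein_id", "domain", "start", "end", "e_value"), "domains")
  out <- data.frame(protein_id = df$protein_id, domain = df$domain,
                    start = as_int_col(df$start, "start", "domains"),
                    end = as_int_col(df$end, "end", "domains"),
                    e_value = as_num_col(df$e_value, "e_value", "domains", positive = TRUE),
                    stringsAsFactors = FALSE)
  if (any(out$start < 1) || any(out$end < out$start)) {
    stopf("domains: require 1 <= start <= end")
  }
  out
}

#' Read an ordered gene table
#'
#' GFF-like TSV with columns `genome_id`, `contig_id`, `gene_index`
#' (0-based, consecutive within contig), `protein_id`, `roles`
#' (`;`-separated role labels, may be empty) and `at_contig_edge`.
#'
#' @param path Path to a TSV file.
#' @return A typed `data.frame` sorted by genome, contig and gene index.
#' @export
read_gene_table <- function(path) {
  df <- read_table_checked(path, c("genome_id", "contig_id", "gene_index",
                                   "protein_id", "roles", "at_contig_edge"), "genes")
  out <- data.frame(genome_id = df$genome_id, contig_id = df$contig_id,
                    gene_index = as_int_col(df$gene_index, "gene_index", "genes"),
                    protein_id = df$protein_id, roles = df$roles,
                    at_contig_edge = as_logical_col(df$at_contig_edge, "at_contig_edge", "genes"),
                    stringsAsFactors = FALSE)
  validate_gene_table(out)
  out
}

validate_gene_table <- function(df) {
  key <- split(df$gene_index, paste(df$genome_id, df$contig_id, sep = "\r"))
  for (k in names(key)) {
    idx <- sort(key[[k]])
    if (anyDuplicated(idx) > 0) stopf("genes: duplicate gene_index within contig '%s'", sub("\r.*", "", k))
    if (!identical(idx, seq(0L, length.out = length(idx)))) {
      stopf("genes: gene_index not consecutive from 0 within contig of genome '%s'", sub("\r.*", "", k))
    }
  }
  invisible(df)
}

#' Read an HMM hit table
#'
#' TSV with columns `protein_id`, `genome_id`, `e_value` (strictly
#' positive), `score`.
#'
#' @param path Path to a TSV file.
#' @return A typed `data.frame`.
#' @export
read_hmm_hits <- function(path) {
  df <- read_table_checked(path, c("protein_id", "genome_id", "e_value", "score"), "hmm_hits")
  data.frame(protein_id = df$protein_id, genome_id = df$genome_id,
             e_value = as_num_col(df$e_value, "e_value", "hmm_hits", positive = TRUE),
             score = as_num_col(df$score, "score", "hmm_hits"),
             stringsAsFactors = FALSE)
}

#' Write pipeline tables to TSV
#'
#' Deterministic TSV writers for the canonical tabular dialects; logical
#' columns are written as `TRUE`/`FALSE`, sets stay `;`-joined.
#'
#' @param df A table as returned by the corresponding reader.
#' @param path Output path.
#' @return The path, invisibly.
#' @rdname write_tables
#' @export
write_cazyme_table <- function(df, path) write_tsv(df[c("protein_id", "hmmer", "diamond", "recommended")], path)

#' @rdname write_tables
#' @export
write_secretion_table <- function(df, path) write_tsv(df[c("protein_id", "call", "probability")], path)

#' @rdname write_tables
#' @export
write_domain_table <- function(df, path) write_tsv(df[c("protein_id", "domain", "start", "end", "e_value")], path)

#' @rdname write_tables
#' @export
write_gene_table <- function(df, path) {
  write_tsv(df[c("genome_id", "contig_id", "gene_index", "protein_id", "roles", "at_contig_edge")], path)
}

#' @rdname write_tables
#' @export
write_hmm_hits <- function(df, path) write_tsv(df[c("protein_id", "genome_id", "e_value", "score")], path)
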