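# Reduce annotated proteins to the set of secreted amylases, typed by clade.
#
# Filter stages, in order: (1) GH13 must be among the recommended CAZyme
# families (after collapsing subfamilies, and accepting multi-family
# recommendations such as GH13 + CBM20); (2) the protein must carry a
# secretion signal; (3) it must contain at least one amylase-type or
# pullulanase-type conserved domain.

#' Collapse a CAZyme subfamily to its family
#'
#' Removes a numeric subfamily suffix: `"GH13_32"` becomes `"GH13"`;
#' strings without a suffix are returned unchanged.
#'
#' @param family Character vector of family strings matching `FAMILY` or
#'   `FAMILY_SUBFAM`.
#' @return Character vector of collapsed family names.
#' @export
collapse_family <- function(family) {
  if (length(family) == 0) return(character(0))
  bad <- family[!grepl(FAMILY_PATTERN, family)]
  if (length(bad) > 0) stopf("malformed family string(s): %s", paste(unique(bad), collapse = ", "))
  sub("_[0-9]+$", "", family)
}

#' Is GH13 among the recommended families of a CAZyme call?
#'
#' `TRUE` iff, after subfamily collapse, `"GH13"` is in the recommended
#' set. Multi-family recommendations (e.g. GH13 together with CBM20) count;
#' an empty recommendation returns `FALSE`.
#'
#' @param recommended A character vector of family strings, or a single
#'   `;`-joined cell as stored in the cazyme table.
#' @return Logical scalar.
#' @export
is_recommended_gh13 <- function(recommended) {
  fams <- if (length(recommended) == 1 && grepl(";", recommended)) {
    split_set(recommended)[[1]]
  } else {
    recommended[!is.na(recommended) & recommended != "" & recommended != "-"]
  }
  if (length(fams) == 0) return(FALSE)
  any(collapse_family(fams) == "GH13")
}

#' Default conserved-domain vocabulary
#'
#' Maps conserved-domain names to functional classes used for filtering and
#' clade typing: `pullulanase` (pullulanase-type alpha-1,6-glycosidase and
#' pullulanase-associated domains), `cmd_like` (catalytic domain of
#' bacterial cyclomaltodextrinases), `alpha14` (alpha-1,4 amylase catalytic
#' domain) and `amylase_other` (maltogenic C-terminal amylase domain).
#' Domains absent from the vocabulary are treated as class `other`. The
#' mapping is an editable data frame, so project-specific domain models can
#' be supplied to [filter_secreted_amylases()] and [assign_clade()].
#'
#' @return A `data.frame` with columns `domain` and `class`.
#' @export
default_domain_vocabulary <- function() {
  data.frame(
    domain = c("pullul_strch", "PUD", "AmyAc_bac_euk_AmyA", "AmyAc_bac_CMD_like_2", "Aamy_C"),
    class = c("pullulanase", "pullulanase", "alpha14", "cmd_like", "amylase_other"),
    stringsAsFactors = FALSE
  )
}

AMYLASE_CLASSES <- c("pullulanase", "alpha14", "cmd_like", "amylase_other")

domain_classes <- function(domain_names, vocabulary) {
  cls <- vocabulary$class[match(domain_names, vocabulary$domain)]
  cls[is.na(cls)] <- "other"
  cls
}

#' Assign an amylase clade from conserved-domain content
#'
#' Clade precedence: `pullulanase` whenever a pullulanase-type domain is
#' present (clade-1 architectures carry an amylase catalytic domain
#' alongside pullulanase domains, so the pullulanase domain is the
#' discriminating signal); otherwise `cmd_like` if the
#' cyclomaltodextrinase-like catalytic domain is present; otherwise
#' `alpha14` if the alpha-1,4 amylase catalytic domain is present;
#' otherwise `unassigned`.
#'
#' @param domain_names Character vector of conserved-domain names.
#' @param vocabulary Domain vocabulary, see [default_domain_vocabulary()].
#' @return One of `"pullulanase"`, `"cmd_like"`, `"alpha14"`,
#'   `"unassigned"`.
#' @export
assign_clade <- function(domain_names, vocabulary = default_domain_vocabulary()) {
  cls <- domain_classes(domain_names, vocabulary)
  if ("pullulanase" %in% cls) return("pullulanase")
  if ("cmd_like" %in% cls) return("cmd_like")
  if ("alpha14" %in% cls) return("alpha14")
  "unassigned"
}

#' Filter annotated proteins to secreted amylases
#'
#' Applies the three-stage secretome filter to a cohort's annotation tables
#' and types each retained amylase by clade. The GH13-recommended proteins
#' are partitioned into `kept`, `dropped_no_signal` (failed the secretion
#' check, which is applied first) and `dropped_no_domain` (secreted but
#' lacking any amylase-type or pullulanase-type domain). Outputs are sorted
#' by `protein_id`, so results are independent of input row order.
#'
#' @param cazyme CAZyme call table ([read_cazyme_table()]).
#' @param secretion Secretion call table ([read_secretion_table()]); every
#'   GH13-recommended protein must be present, otherwise the annotation is
#'   incomplete and an error is raised.
#' @param domains Conserved-domain hit table ([read_domain_table()]).
#' @param vocabulary Domain vocabulary ([default_domain_vocabulary()]).
#' @param genes Optional ordered gene table ([read_gene_table()]) used to
#'   attach `genome_id` and locus coordinates to kept amylases.
#' @return A list with `kept` (data frame: `protein_id`, `genome_id`,
#'   `clade`, `domain_names`, `contig_id`, `gene_index`),
#'   `dropped_no_signal` and `dropped_no_domain` (character vectors of
#'   protein ids).
#' @export
filter_secreted_amylases <- function(cazyme, secretion, domains,
                                     vocabulary = default_domain_vocabulary(),
                                     genes = NULL) {
  stopifnot(is.data.frame(cazyme), is.data.frame(secretion), is.data.frame(domains))
  dup <- unique(cazyme$protein_id[duplicated(cazyme$protein_id)])
  if (length(dup) > 0) stopf("duplicate protein_id(s) in cazyme table: %s", paste(dup, collapse = ", "))

  rec <- split_set(cazyme$recommended)
  gh13 <- vapply(rec, function(f) length(f) > 0 && any(collapse_family(f) == "GH13"), logical(1))
  cand <- sort(cazyme$protein_id[gh13])
  if (length(cand) == 0) {
    return(list(kept = empty_amylase_table(), dropped_no_signal = character(0),
                dropped_no_domain = character(0)))
  }

  missing_sec <- setdiff(cand, secretion$protein_id)
  if (length(missing_sec) > 0) {
    stopf("incomplete annotation: GH13-recommended protein(s) absent from secretion table: %s",
          paste(missing_sec, collapse = ", "))
  }
  is_sec <- secretion$is_secreted %||%
    !(toupper(secretion$call) %in% c("OTHER", "NONE", ""))
  secreted <- stats::setNames(is_sec, secretion$protein_id)[cand]

  dropped_no_signal <- cand[!secreted]
  pass_signal <- cand[secreted]

  dom_by_prot <- split(domains$domain, domains$protein_id)
  has_amy_dom <- vapply(pass_signal, function(p) {
    any(domain_classes(dom_by_prot[[p]] %||% character(0), vocabulary) %in% AMYLASE_CLASSES)
  }, logical(1))
  dropped_no_domain <- pass_signal[!has_amy_dom]
  kept_ids <- pass_signal[has_amy_dom]

  if (length(kept_ids) == 0) {
    return(list(kept = empty_amylase_table(), dropped_no_signal = dropped_no_signal,
                dropped_no_domain = dropped_no_domain))
  }

  doms <- lapply(kept_ids, function(p) sort(unique(dom_by_prot[[p]] %||% character(0))))
  clade <- vapply(doms, assign_clade, character(1), vocabulary = vocabulary)
  kept <- data.frame(protein_id = kept_ids,
                     genome_id = NA_character_,
                     clade = clade,
                     domain_names = join_set(doms),
                     contig_id = NA_character_,
                     gene_index = NA_integer_,
                     stringsAsFactors = FALSE)
  if (!is.null(genes)) {
    i <- match(kept$protein_id, genes$protein_id)
    kept$genome_id <- genes$genome_id[i]
    kept$contig_id <- genes$contig_id[i]
    kept$gene_index <- genes$gene_index[i]
  }
  rownames(kept) <- NULL
  list(kept = kept, dropped_no_signal = dropped_no_signal,
       dropped_no_domain = dropped_no_domain)
}

empty_amylase_table <- function() {
  data.frame(protein_id = character(0), genome_id = character(0),
             clade = character(0), domain_names = character(0),
             contig_id = character(0), gene_index = integer(0),
             stringsAsFactors = FALSE)
}

#' @rdname write_tables
#' @export
write_amylase_table <- function(df, path) {
  write_tsv(df[c("protein_id", "genome_id", "clade", "domain_names", "contig_id", "gene_index")], path)
}

#' Read a retained-amylase table written by [write_amylase_table()]
#' @param path Path to a TSV file.
#' @return A typed `data.frame`.
#' @export
read_amylase_table <- function(path) {
  df <- read_table_checked(path, c("protein_id", "genome_id", "clade",
                                   "domain_names", "contig_id", "gene_index"), "amylases")
  df$gene_index <- as_int_col(df$gene_index, "gene_index", "amylases")
  df
}
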