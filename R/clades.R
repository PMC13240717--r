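# Midpoint rooting, tree-cut clade extraction, consensus sequences and
# consensus-nearest representative selection.

check_branch_lengths <- function(tree) {
  if (is.null(tree$edge.length) || length(tree$edge.length) != nrow(tree$edge) ||
      anyNA(tree$edge.length)) {
    stopf("tree is missing branch lengths")
  }
  if (any(tree$edge.length < 0)) stopf("negative branch lengths are not allowed")
  invisible(tree)
}

#' Midpoint-root a tree
#'
#' Places the root on the edge at the exact midpoint of the longest
#' leaf-to-leaf path, so the two maximal root-to-leaf distances are equal
#' (within 1e-9). Internal-node support labels are carried along verbatim.
#'
#' @param tree An unrooted (or rooted) `phylo` object with complete,
#'   non-negative branch lengths and at least two leaves.
#' @return A rooted `phylo` object.
#' @export
midpoint_root <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (ape::Ntip(tree) < 2) stopf("midpoint rooting needs at least two leaves")
  check_branch_lengths(tree)
  if (ape::Ntip(tree) == 2) {
    tot <- sum(tree$edge.length)
    tree$edge.length <- rep(tot / 2, nrow(tree$edge))
    attr(tree, "order") <- NULL
    return(tree)
  }
  phangorn::midpoint(tree, node.labels = "support")
}

#' Root-to-leaf distances of a rooted tree
#' @param tree A rooted `phylo` with branch lengths.
#' @return Named numeric vector of distances from the root to each leaf.
#' @export
root_to_leaf_depths <- function(tree) {
  check_branch_lengths(tree)
  d <- ape::node.depth.edgelength(tree)
  stats::setNames(d[seq_len(ape::Ntip(tree))], tree$tip.label)
}

# descendant tip sets (and full descendant node sets, self included) for
# every node of a phylo, as lists indexed by node id
descendant_sets <- function(tree) {
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  tips <- vector("list", ntip + nnode)
  nodes <- vector("list", ntip + nnode)
  for (i in seq_len(ntip + nnode)) nodes[[i]] <- i
  for (i in seq_len(ntip)) tips[[i]] <- i
  edge <- tree$edge
  for (e in ape::postorder(tree)) {  # children before parents
    parent <- edge[e, 1]; child <- edge[e, 2]
    tips[[parent]] <- c(tips[[parent]], tips[[child]])
    nodes[[parent]] <- c(nodes[[parent]], nodes[[child]])
  }
  list(tips = tips, nodes = nodes)
}

#' Cut a rooted tree into k clades (greedy deepest-split rule)
#'
#' Starting from the whole tree as one clade, iteratively removes the edge
#' whose cut minimizes the maximum within-clade root-to-leaf span, until k
#' clades remain. A clade's span is measured from the deepest common
#' ancestor of its leaves (unifurcations created by cuts are collapsed), so
#' each clade is a connected subtree. Ties are broken by edge order in the
#' tree's edge matrix; clades are numbered by their first leaf in tip
#' order. The cut rule is a deterministic implementation choice for
#' delimiting the major clades a practitioner would read off a tree by eye.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param k Number of clades, `1 <= k <=` number of leaves.
#' @return A list of class `clade_partition` with `k` and `assignments`
#'   (named integer vector, leaf label -> clade index in `1..k`).
#' @export
extract_clades <- function(tree, k) {
  stopifnot(inherits(tree, "phylo"))
  check_branch_lengths(tree)
  ntip <- ape::Ntip(tree)
  if (k < 1 || k != floor(k)) stopf("k must be a positive integer")
  if (k > ntip) stopf("k = %d exceeds the number of leaves (%d)", k, ntip)
  if (!ape::is.rooted(tree)) stopf("extract_clades expects a rooted tree (see midpoint_root)")

  depths <- ape::node.depth.edgelength(tree)
  desc <- descendant_sets(tree)
  nnodes <- ntip + tree$Nnode
  # nodes sorted by depth, deepest first, for LCA search
  node_order <- order(depths, decreasing = TRUE)

  lca_depth <- function(tips) {
    if (length(tips) == 1) return(depths[tips])
    for (v in node_order) {
      if (length(desc$tips[[v]]) >= length(tips) && all(tips %in% desc$tips[[v]])) {
        return(depths[v])
      }
    }
    depths[ntip + 1]  # root
  }
  span <- function(tips) max(depths[tips]) - lca_depth(tips)

  # component id per node; cutting edge (u,v) moves v's still-attached
  # subtree into a fresh component
  comp <- rep(1L, nnodes)
  edge <- tree$edge
  comp_tips <- function() split(seq_len(ntip), comp[seq_len(ntip)])

  while (length(unique(comp[seq_len(ntip)])) < k) {
    groups <- comp_tips()
    spans <- vapply(groups, span, numeric(1))
    best <- NULL
    for (e in seq_len(nrow(edge))) {
      u <- edge[e, 1]; v <- edge[e, 2]
      if (comp[u] != comp[v]) next  # edge already severed below a cut
      cid <- comp[v]
      g <- groups[[as.character(cid)]]
      g1 <- intersect(desc$tips[[v]], g)
      if (length(g1) == 0 || length(g1) == length(g)) next
      g2 <- setdiff(g, g1)
      others <- spans[names(spans) != as.character(cid)]
      obj <- max(c(others, span(g1), span(g2)))
      if (is.null(best) || obj < best$obj - 1e-12) {
        best <- list(obj = obj, v = v, cid = cid)
      }
    }
    if (is.null(best)) stopf("cannot split further: fewer than k distinct subtrees")
    sub <- desc$nodes[[best$v]]
    newid <- max(comp) + 1L
    comp[sub[comp[sub] == best$cid]] <- newid
  }

  groups <- unname(comp_tips())
  first_tip <- vapply(groups, min, numeric(1))
  ord <- order(first_tip)
  assignments <- integer(ntip)
  for (i in seq_along(ord)) assignments[groups[[ord[i]]]] <- i
  structure(list(k = k, assignments = stats::setNames(assignments, tree$tip.label)),
            class = "clade_partition")
}

#' @export
print.clade_partition <- function(x, ...) {
  cat(sprintf("clade_partition: %d clades, sizes %s\n", x$k,
              paste(tabulate(x$assignments, x$k), collapse = "/")))
  invisible(x)
}

#' Consensus sequence of an alignment subset
#'
#' Per column, the most frequent residue among the member sequences. Under
#' the default `gap_policy = "ignore_gaps"`, gaps are excluded from the
#' count and an all-gap column emits `-`. Under `"include_gaps"` the gap
#' character competes like any residue. Frequency ties are broken by the
#' lexicographically smallest character.
#'
#' @param alignment An `amy_alignment`.
#' @param member_ids Non-empty subset of alignment ids (default: all).
#' @param gap_policy `"ignore_gaps"` or `"include_gaps"`.
#' @return A single consensus string of length `alignment$length`.
#' @export
consensus_sequence <- function(alignment, member_ids = NULL,
                               gap_policy = c("ignore_gaps", "include_gaps")) {
  gap_policy <- match.arg(gap_policy)
  member_ids <- member_ids %||% alignment$id
  if (length(member_ids) == 0) stopf("consensus_sequence: empty member set")
  m <- alignment_matrix(alignment, member_ids)
  cons <- apply(m, 2, function(col) {
    if (gap_policy == "ignore_gaps") col <- col[col != "-"]
    if (length(col) == 0) return("-")
    tab <- table(col)
    cands <- names(tab)[tab == max(tab)]
    sort(cands, method = "radix")[1]
  })
  paste(cons, collapse = "")
}

#' Select the consensus-nearest representative of a clade
#'
#' Returns the member whose column-wise identity to the clade consensus is
#' maximal. Identity is the fraction of identical columns over the columns
#' where neither the member nor the consensus is gapped; a member with no
#' such columns has identity 0. Ties are broken by the order of
#' `member_ids`.
#'
#' @inheritParams consensus_sequence
#' @return The protein id of the selected representative.
#' @export
select_representative <- function(alignment, member_ids = NULL,
                                  gap_policy = c("ignore_gaps", "include_gaps")) {
  gap_policy <- match.arg(gap_policy)
  member_ids <- member_ids %||% alignment$id
  if (length(member_ids) == 0) stopf("select_representative: empty member set")
  cons <- strsplit(consensus_sequence(alignment, member_ids, gap_policy), "", fixed = TRUE)[[1]]
  m <- alignment_matrix(alignment, member_ids)
  sims <- vapply(seq_along(member_ids), function(i) {
    ok <- m[i, ] != "-" & cons != "-"
    if (!any(ok)) return(0)
    mean(m[i, ok] == cons[ok])
  }, numeric(1))
  member_ids[which.max(sims)]
}
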