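# core_io: phylogenetic tree input and distance plumbing (ape-backed).

#' Read a rooted newick tree
#'
#' Thin wrapper around [ape::read.tree()] that enforces the conventions
#' the rest of the package relies on: branch lengths present (missing or
#' `NA` lengths are set to 0 with a warning) and unique tip labels.
#'
#' @param path Path to a newick file, or a newick string starting with "(".
#' @return An [ape::phylo] object.
#' @export
read_tree <- function(path) {
  tr <- if (grepl("^\\s*\\(", path)) ape::read.tree(text = path)
        else ape::read.tree(path)
  if (is.null(tr)) stop("could not parse newick input", call. = FALSE)
  if (is.null(tr$edge.length)) {
    warning("tree has no branch lengths; setting all to 0")
    tr$edge.length <- rep(0, nrow(tr$edge))
  }
  if (anyNA(tr$edge.length)) {
    warning("tree has missing branch lengths; setting them to 0")
    tr$edge.length[is.na(tr$edge.length)] <- 0
  }
  if (any(tr$edge.length < 0))
    stop("negative branch lengths are not allowed", call. = FALSE)
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip labels", call. = FALSE)
  tr
}

# Error unless every id in `ids` is a tip of `tree`.
check_tip_coverage <- function(tree, ids) {
  miss <- setdiff(ids, tree$tip.label)
  if (length(miss))
    stop("taxa absent from the tree: ",
         paste(utils::head(miss, 10), collapse = ", "),
         if (length(miss) > 10) sprintf(" (+%d more)", length(miss) - 10),
         call. = FALSE)
  invisible(TRUE)
}

#' Patristic distances between tips
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @param tips Optional tip subset/order; defaults to all tips.
#' @return Symmetric matrix of branch-length path distances.
#' @export
patristic_distances <- function(tree, tips = NULL) {
  d <- ape::cophenetic.phylo(tree)
  if (!is.null(tips)) {
    check_tip_coverage(tree, tips)
    d <- d[tips, tips, drop = FALSE]
  }
  d
}

# Edge-by-sample presence incidence: for each edge of `tree` (row of
# tree$edge), TRUE for sample s iff any tip descending from that edge's
# child node is present in s. `presence` is a logical samples x tips
# matrix with colnames covering tree$tip.label order lookups.
edge_incidence <- function(tree, presence) {
  check_tip_coverage(tree, colnames(presence))
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  ns <- nrow(presence)
  occ <- matrix(FALSE, nrow = nnode, ncol = ns)
  idx <- match(tr$tip.label, colnames(presence))
  has <- !is.na(idx)
  occ[seq_len(ntip)[has], ] <- t(presence[, idx[has], drop = FALSE])
  B <- matrix(FALSE, nrow = nrow(tr$edge), ncol = ns)
  for (e in seq_len(nrow(tr$edge))) {
    child <- tr$edge[e, 2L]
    B[e, ] <- occ[child, ]
    parent <- tr$edge[e, 1L]
    occ[parent, ] <- occ[parent, ] | occ[child, ]
  }
  list(incidence = B, lengths = tr$edge.length,
       sample_ids = rownames(presence))
}
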