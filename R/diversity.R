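# diversity: alpha indices and beta dissimilarity matrices.

#' Chao1 richness estimate (bias-corrected)
#'
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))`, with F1/F2 the singleton and
#' doubleton counts. The bias-corrected denominator keeps the estimate
#' defined when no doubletons are observed.
#'
#' @param x Nonnegative integer count vector for one sample.
#' @return Estimated richness (0 for an all-zero vector).
#' @export
chao1 <- function(x) {
  x <- x[x > 0]
  if (!length(x)) return(0)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  length(x) + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Shannon-Wiener diversity (natural log)
#'
#' @param x Nonnegative count (or abundance) vector.
#' @return `-sum(p log p)` over positive entries, in nats; `NA` if the
#'   vector sums to zero.
#' @export
shannon <- function(x) {
  tot <- sum(x)
  if (tot <= 0) return(NA_real_)
  p <- x[x > 0] / tot
  -sum(p * log(p))
}

#' Faith's phylogenetic diversity
#'
#' Sum of branch lengths of the minimal subtree connecting the sample's
#' taxa to the root (root-inclusive convention: a single-tip sample
#' scores its root-to-tip path length).
#'
#' @param present Character vector of present taxon ids (or a logical /
#'   count vector named by taxon).
#' @param tree An [ape::phylo] tree with branch lengths.
#' @return Total spanned branch length; 0 for an empty sample.
#' @export
faith_pd <- function(present, tree) {
  if (!is.character(present)) {
    stopifnot(!is.null(names(present)))
    present <- names(present)[present > 0]
  }
  if (!length(present)) return(0)
  check_tip_coverage(tree, present)
  pres <- matrix(TRUE, nrow = 1, ncol = length(present),
                 dimnames = list("s", present))
  ei <- edge_incidence(tree, pres)
  sum(ei$lengths[ei$incidence[, 1L]])
}

#' Alpha diversity table
#'
#' Observed richness, Chao1, Shannon and (when a tree is supplied) Faith
#' PD for every sample.
#'
#' @param counts Count matrix (samples x ASVs).
#' @param tree Optional [ape::phylo] covering the table's ASVs.
#' @return Data frame, one row per sample.
#' @export
alpha_diversity <- function(counts, tree = NULL) {
  counts <- validate_asv_table(counts)
  out <- data.frame(
    sample_id = rownames(counts),
    observed_richness = rowSums(counts > 0),
    chao1 = apply(counts, 1, chao1),
    shannon = apply(counts, 1, shannon),
    stringsAsFactors = FALSE)
  if (!is.null(tree)) {
    pres <- counts > 0
    check_tip_coverage(tree, colnames(counts)[colSums(pres) > 0])
    ei <- edge_incidence(tree, pres)
    out$faith_pd <- as.numeric(crossprod(ei$incidence, ei$lengths))
  }
  rownames(out) <- out$sample_id
  out
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = sum |x_i - y_i| / sum (x_i + y_i)` over all taxa; values
#' in `[0, 1]`.
#'
#' @param counts Count (or abundance) matrix, samples x taxa.
#' @return Symmetric matrix with zero diagonal and sample ids.
#' @export
bray_curtis <- function(counts) {
  counts <- as.matrix(counts)
  rs <- rowSums(counts)
  if (any(rs == 0)) warning("samples with zero total: pairs involving ",
                            "them are undefined (NA)")
  num <- as.matrix(stats::dist(counts, method = "manhattan"))
  den <- outer(rs, rs, "+")
  d <- num / den
  d[den == 0] <- NA_real_
  diag(d) <- 0
  dimnames(d) <- list(rownames(counts), rownames(counts))
  d
}

#' Unweighted UniFrac distance matrix
#'
#' For each pair of samples, the fraction of spanned branch length
#' unique to one of the two: `sum(l_b |I_A - I_B|) / sum(l_b max(I_A,
#' I_B))` over branches `b`, where `I_X(b)` indicates whether any tip
#' below `b` is present in X. Presence/absence only; computed after
#' rarefaction in the standard workflow.
#'
#' @param counts Count matrix (samples x ASVs).
#' @param tree [ape::phylo] whose tips cover all ASVs with positive
#'   counts.
#' @return Symmetric matrix in `[0, 1]` with zero diagonal.
#' @export
unweighted_unifrac <- function(counts, tree) {
  counts <- validate_asv_table(counts)
  pres <- counts > 0
  check_tip_coverage(tree, colnames(counts)[colSums(pres) > 0])
  ei <- edge_incidence(tree, pres)
  B <- ei$incidence * 1            # edges x samples, 0/1
  l <- ei$lengths
  shared <- crossprod(B * l, B)    # sum l over branches present in both
  spanned <- as.numeric(crossprod(B, l))  # per-sample spanned length
  union <- outer(spanned, spanned, "+") - shared
  d <- 1 - shared / union
  d[union == 0] <- NA_real_
  diag(d) <- 0
  dimnames(d) <- list(rownames(counts), rownames(counts))
  d
}
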