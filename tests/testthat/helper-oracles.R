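# Independent brute-force oracles and shared fixtures. These
# deliberately avoid the package's internal code paths: naive loops,
# explicit recursion and enumeration only.

# ---- fixtures -------------------------------------------------------

toy_tree <- function() read_tree("((A:1,B:1):1,C:2);")

random_table <- function(n_samples, n_taxa, max_count = 50, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n_samples * n_taxa, lambda = runif(1, 1, 8)),
              n_samples, n_taxa)
  m[sample(length(m), length(m) %/% 3)] <- 0L
  storage.mode(m) <- "integer"
  dimnames(m) <- list(paste0("S", seq_len(n_samples)),
                      paste0("ASV", seq_len(n_taxa)))
  m
}

random_dist <- function(n, seed = 1, ids = paste0("S", seq_len(n))) {
  set.seed(seed)
  d <- as.matrix(dist(matrix(rnorm(n * 3), n)))
  dimnames(d) <- list(ids, ids)
  d
}

# all permutations of 1..n, rows; independent re-implementation
perms_oracle <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  do.call(rbind, lapply(seq_len(n), function(k) {
    sub <- perms_oracle(n - 1)
    cbind(k, matrix(setdiff(seq_len(n), k)[sub], nrow(sub)))
  }))
}

# ---- diversity oracles ---------------------------------------------

bray_oracle <- function(x, y) sum(abs(x - y)) / sum(x + y)

# Recursive descendant-tip listing, independent of edge_incidence()
descendants_oracle <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, descendants_oracle, tree = tree))
}

unifrac_oracle <- function(tree, present_a, present_b) {
  num <- den <- 0
  for (e in seq_len(nrow(tree$edge))) {
    tips <- descendants_oracle(tree, tree$edge[e, 2])
    ia <- any(tips %in% present_a)
    ib <- any(tips %in% present_b)
    l <- tree$edge.length[e]
    num <- num + l * abs(ia - ib)
    den <- den + l * max(ia, ib)
  }
  num / den
}

faith_oracle <- function(tree, present) {
  tot <- 0
  for (e in seq_len(nrow(tree$edge))) {
    tips <- descendants_oracle(tree, tree$edge[e, 2])
    if (any(tips %in% present)) tot <- tot + tree$edge.length[e]
  }
  tot
}

# ---- assembly oracles ----------------------------------------------

bmntd_oracle <- function(xa, xb, D, weighted = TRUE) {
  ta <- names(xa)[xa > 0]; tb <- names(xb)[xb > 0]
  fa <- if (weighted) xa[ta] / sum(xa[ta]) else rep(1 / length(ta),
                                                    length(ta))
  fb <- if (weighted) xb[tb] / sum(xb[tb]) else rep(1 / length(tb),
                                                    length(tb))
  s1 <- sum(vapply(seq_along(ta), function(i)
    fa[i] * min(D[ta[i], tb]), 1.0))
  s2 <- sum(vapply(seq_along(tb), function(j)
    fb[j] * min(D[tb[j], ta]), 1.0))
  0.5 * (s1 + s2)
}

# betaNTI by exhaustive tip-relabelling enumeration
bnti_exhaustive_oracle <- function(xa, xb, tree, weighted = TRUE) {
  D <- ape::cophenetic.phylo(tree)
  tips <- tree$tip.label
  obs <- bmntd_oracle(xa, xb, D, weighted)
  P <- perms_oracle(length(tips))
  nulls <- apply(P, 1, function(p) {
    Dp <- D[p, p]
    dimnames(Dp) <- list(tips, tips)
    bmntd_oracle(xa, xb, Dp, weighted)
  })
  (obs - mean(nulls)) / sd(nulls)
}

# ---- graph oracle ---------------------------------------------------

betweenness_oracle <- function(g) {
  n <- igraph::vcount(g)
  btw <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    sp <- suppressWarnings(
      igraph::all_shortest_paths(g, from = s, to = t)$res)
    if (!length(sp)) next
    for (path in sp) {
      inner <- setdiff(as.integer(path), c(s, t))
      btw[inner] <- btw[inner] + 1 / length(sp)
    }
  }
  btw
}

# ---- misc -----------------------------------------------------------

# ANOSIM statistic recomputed from first principles
anosim_oracle_stat <- function(d, groups) {
  v <- d[lower.tri(d)]
  rk <- rank(v)
  same <- outer(groups, groups, "==")[lower.tri(d)]
  n <- nrow(d)
  (mean(rk[!same]) - mean(rk[same])) / (n * (n - 1) / 4)
}

expect_symmetric01 <- function(d) {
  expect_true(max(abs(d - t(d)), na.rm = TRUE) < 1e-12)
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= -1e-12 & d <= 1 + 1e-12, na.rm = TRUE))
}
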