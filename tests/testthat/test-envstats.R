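# env_stats: Mantel, partial Mantel, env distances, VPA, rank tests

test_that("mantel: self-correlation, exact enumeration, vegan agreement", {
  d <- random_dist(7, seed = 1)
  m <- mantel(d, d, n_perm = 49, seed = 1)
  expect_equal(m$r, 1)
  expect_gte(m$p_value, 1 / 50)
  # exact n = 4 oracle
  d1 <- random_dist(4, seed = 2); d2 <- random_dist(4, seed = 3)
  ex <- mantel(d1, d2, exact = TRUE)
  rfun <- function(perm) {
    cor(rank(d1[lower.tri(d1)]),
        rank(d2[perm, perm][lower.tri(d2)]))
  }
  rs <- apply(perms_oracle(4), 1, rfun)
  expect_equal(ex$p_value, mean(rs >= rfun(1:4) - 1e-12))
  # statistic agrees with vegan (spearman and pearson)
  da <- random_dist(9, seed = 4); db <- random_dist(9, seed = 5)
  for (meth in c("spearman", "pearson")) {
    vm <- vegan::mantel(as.dist(da), as.dist(db), method = meth,
                        permutations = 9)
    mm <- mantel(da, db, method = meth, n_perm = 9, seed = 1)
    expect_equal(mm$r, unname(vm$statistic), tolerance = 1e-12)
  }
  expect_error(mantel(matrix(0, 5, 5), da[1:5, 1:5]), "constant")
})

test_that("partial mantel: control collapses or preserves the signal", {
  set.seed(6)
  n <- 12
  base <- matrix(rnorm(n * 2), n)
  dA <- as.matrix(dist(base))
  dB <- as.matrix(dist(base + rnorm(n * 2, sd = 0.1)))
  dC <- random_dist(n, seed = 7)
  ids <- paste0("S", 1:n)
  dimnames(dA) <- dimnames(dB) <- dimnames(dC) <- list(ids, ids)
  # dC a near-copy of dB: control removes almost all the signal
  dBc <- as.matrix(dist(base + rnorm(n * 2, sd = 0.1) +
                          rnorm(n * 2, sd = 0.02)))
  dimnames(dBc) <- list(ids, ids)
  p0 <- partial_mantel(dA, dB, dBc, n_perm = 49, seed = 1)
  expect_lt(abs(p0$r), abs(mantel(dA, dB, n_perm = 1, seed = 1)$r))
  # exactly collinear control is refused
  expect_error(partial_mantel(dA, dB, dB + 0), "collinear")
  # dA == dB with independent control: r ~ 1
  p1 <- partial_mantel(dA, dA + 0, dC, n_perm = 49, seed = 1)
  expect_gt(p1$r, 0.95)
  # uncorrelated control: partial r close to simple r
  ps <- partial_mantel(dA, dB, dC, n_perm = 49, seed = 1)
  ms <- mantel(dA, dB, n_perm = 49, seed = 1)
  expect_lt(abs(ps$r - ms$r), 0.1)
  expect_error(partial_mantel(dA, dB, dA + 0), "collinear")
})

test_that("env_distance is the absolute difference of z-scores", {
  v <- setNames(c(0, 1, 3), paste0("S", 1:3))
  d <- env_distance(v)
  s <- sd(v)
  expect_equal(d["S1", "S2"], 1 / s)
  expect_equal(d["S1", "S3"], 3 / s)
  expect_equal(d["S2", "S3"], 2 / s)
  # affine invariance
  expect_equal(env_distance(v * 7 + 100), d)
  expect_warning(dz <- env_distance(setNames(rep(2, 3), names(v))),
                 "constant")
  expect_true(all(dz == 0))
  meta <- data.frame(TOC = v, row.names = names(v))
  expect_equal(env_distance(meta, "TOC"), d)
})

test_that("vpa: definition collapse, symmetry, vegan agreement", {
  set.seed(8)
  n <- 40
  X1 <- matrix(rnorm(n * 2), n, dimnames = list(NULL, c("a1", "a2")))
  X2 <- matrix(rnorm(n * 2), n, dimnames = list(NULL, c("b1", "b2")))
  Y <- matrix(rpois(n * 10, 20), n)
  v <- vpa_two_sets(Y, X1, X2)
  expect_equal(sum(v$raw), 1, tolerance = 1e-12)
  vs <- vpa_two_sets(Y, X2, X1)
  expect_equal(vs$raw[["a"]], v$raw[["c"]], tolerance = 1e-12)
  expect_equal(vs$raw[["b"]], v$raw[["b"]], tolerance = 1e-12)
  expect_equal(vs$raw[["d"]], v$raw[["d"]], tolerance = 1e-12)
  # empty set2 collapses to a = adj(set1)
  v0 <- vpa_two_sets(Y, X1, NULL)
  expect_equal(v0$raw[["a"]], v0$adj_set1)
  expect_equal(v0$raw[["b"]], 0)
  expect_equal(v0$raw[["c"]], 0)
  # vegan::varpart gives the same adjusted fractions
  vp <- vegan::varpart(vegan::decostand(Y, "hellinger"),
                       scale(X1), scale(X2))
  # vegan's indfract rows are (pure1, pure2, shared, residual)
  ind <- vp$part$indfract$Adj.R.square
  expect_equal(unname(v$raw[c("a", "c", "b", "d")]), ind,
               tolerance = 1e-6)
  # collinear predictors are reported
  X1c <- cbind(X1, a3 = X1[, 1] * 2)
  expect_error(vpa_two_sets(Y, X1c, X2), "collinear")
})

test_that("vpa: perfect fit in set1 leaves no residual", {
  set.seed(9)
  n <- 50
  X1 <- scale(matrix(rnorm(n * 2), n))
  X2 <- scale(matrix(rnorm(n * 2), n))
  Y <- X1 %*% matrix(c(1, 2, -1, 0.5), 2)   # exactly linear in set1
  v <- vpa_two_sets(Y, X1, X2, hellinger = FALSE)
  expect_lt(abs(v$raw[["d"]]), 0.01)
  expect_lt(abs(v$raw[["c"]]), 0.01)
  expect_gt(v$raw[["a"]], 0.9)
})

test_that("wilcoxon: exact enumeration, identity case, rank invariance", {
  w <- wilcoxon_rank_sum(c(1, 2), c(3, 4), alternative = "greater")
  expect_equal(w$p_value, 1)            # rank sum of x is the minimum
  w2 <- wilcoxon_rank_sum(c(1, 2), c(3, 4), alternative = "less")
  expect_equal(w2$p_value, 1 / 6)       # most extreme of C(4,2) splits
  wi <- wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))
  expect_equal(wi$p_value, 1)
  # invariance under common monotone transform
  x <- c(0.3, 2, 5, 9); y <- c(1, 4, 6, 11)
  expect_equal(wilcoxon_rank_sum(x, y)$p_value,
               wilcoxon_rank_sum(exp(x), exp(y))$p_value)
  # agreement with stats::wilcox.test (exact, no ties)
  wt <- wilcox.test(x, y, exact = TRUE)
  expect_equal(wilcoxon_rank_sum(x, y)$p_value, wt$p.value)
  # large-sample normal path with ties is a sane approximation
  set.seed(10)
  xl <- round(rnorm(30), 1); yl <- round(rnorm(30) + 0.1, 1)
  pl <- wilcoxon_rank_sum(xl, yl)$p_value
  pw <- wilcox.test(xl, yl, exact = FALSE, correct = FALSE)$p.value
  expect_equal(pl, pw, tolerance = 1e-10)
})

test_that("kruskal-wallis: hand value, ties, base-R agreement", {
  # perfect ordering of three groups of two: H = 12/42 * 16 = 32/7
  kw <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(kw$statistic, 32 / 7)
  expect_equal(kw$statistic,
               unname(kruskal.test(list(c(1, 2), c(3, 4),
                                        c(5, 6)))$statistic))
  expect_equal(kw$df, 2)
  ident <- kruskal_wallis(list(c(2, 2), c(2, 2)))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)
  g <- list(c(1, 5, 2, 2), c(3, 3, 7), c(2, 8, 9, 4))
  kb <- kruskal.test(g)
  km <- kruskal_wallis(g)
  expect_equal(km$statistic, unname(kb$statistic), tolerance = 1e-12)
  expect_equal(km$p_value, kb$p.value, tolerance = 1e-12)
  expect_equal(km$p_value,
               kruskal_wallis(lapply(g, function(v) v^3))$p_value)
})
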