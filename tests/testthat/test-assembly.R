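# assembly: betaMNTD/betaNTI, Raup-Crick, process classification

test_that("beta_mntd hand values and double-loop oracle", {
  tr <- toy_tree()
  expect_equal(beta_mntd(c(A = 1), c(B = 1), tr), 2)
  expect_equal(beta_mntd(c(A = 3, B = 1), c(A = 3, B = 1), tr), 0)
  D <- patristic_distances(tr)
  for (seed in 1:5) {
    set.seed(seed)
    tr4 <- simulate_tree(4, seed = seed)
    D4 <- patristic_distances(tr4)
    xa <- setNames(rpois(4, 2), tr4$tip.label)
    xb <- setNames(rpois(4, 2), tr4$tip.label)
    if (sum(xa) == 0 || sum(xb) == 0) next
    expect_equal(beta_mntd(xa, xb, tr4),
                 bmntd_oracle(xa, xb, D4), tolerance = 1e-12)
    expect_equal(beta_mntd(xa, xb, tr4, weighted = FALSE),
                 bmntd_oracle(xa, xb, D4, weighted = FALSE),
                 tolerance = 1e-12)
  }
  expect_error(beta_mntd(c(A = 0), c(B = 1), tr), "empty")
  # matrix form agrees with pairwise form
  m <- rbind(u = c(2, 1, 0), v = c(0, 1, 4), w = c(1, 1, 1))
  colnames(m) <- c("A", "B", "C")
  bm <- beta_mntd_matrix(m, tr)
  expect_equal(bm["u", "v"], beta_mntd(m["u", ], m["v", ], tr))
  expect_true(all(bm == t(bm)) && all(diag(bm) == 0))
})

test_that("beta_nti exhaustive enumeration equals the brute-force oracle", {
  for (seed in 1:3) {
    tr <- simulate_tree(4, seed = seed + 40)
    set.seed(seed)
    cnt <- matrix(rpois(8, 3) + 1L, 2, 4,
                  dimnames = list(c("sA", "sB"), tr$tip.label))
    cnt[1, sample(4, 1)] <- 0L
    z <- beta_nti(cnt, tr, exhaustive = TRUE)
    zo <- bnti_exhaustive_oracle(cnt[1, ], cnt[2, ], tr)
    expect_equal(z["sA", "sB"], zo, tolerance = 1e-10)
  }
})

test_that("beta_nti degenerate and sign-bound cases", {
  # star tree, equal branch lengths: every relabelling identical
  star <- read_tree("(A:1,B:1,C:1,D:1);")
  cnt <- rbind(s1 = c(1L, 1L, 0L, 0L), s2 = c(0L, 0L, 1L, 1L))
  colnames(cnt) <- star$tip.label
  z <- beta_nti(cnt, star, n_null = 30, seed = 1)
  expect_true(is.na(z["s1", "s2"]))
  expect_equal(attr(z, "n_degenerate"), 1)
  # identical communities: obs = 0 <= all nulls, so z <= 0 (or NA)
  tr <- simulate_tree(8, seed = 3)
  cnt2 <- rbind(s1 = rep(1L, 8), s2 = rep(1L, 8),
                s3 = c(rep(0L, 4), rep(2L, 4)))
  colnames(cnt2) <- tr$tip.label
  z2 <- beta_nti(cnt2, tr, n_null = 60, seed = 2)
  expect_true(is.na(z2["s1", "s2"]) || z2["s1", "s2"] <= 0)
  # reproducibility
  z3 <- beta_nti(cnt2, tr, n_null = 60, seed = 2)
  expect_identical(z2, z3)
})

test_that("raup_crick_bray bounds and extremes", {
  set.seed(9)
  m <- random_table(6, 50, seed = 12) + 0L
  m <- m[rowSums(m) > 0, ]
  rc <- raup_crick_bray(m, n_null = 99, seed = 5)
  expect_symmetric01(abs(rc))
  expect_true(all(rc >= -1 & rc <= 1))
  # two identical samples drawn from a 50-taxon pool -> RC near -1
  pool <- rpois(50, 3) + 1L
  ident <- rbind(s1 = pool, s2 = pool,
                 s3 = rpois(50, 3) + 1L, s4 = rpois(50, 3) + 1L)
  colnames(ident) <- paste0("t", 1:50)
  rci <- raup_crick_bray(ident, n_null = 199, seed = 6)
  expect_lt(rci["s1", "s2"], -0.9)
  # obs larger than every null draw -> RC ~ +1: two disjoint samples
  disj <- rbind(a = c(rep(5L, 25), rep(0L, 25)),
                b = c(rep(0L, 25), rep(5L, 25)),
                c = rep(2L, 50), d = rep(2L, 50))
  colnames(disj) <- paste0("t", 1:50)
  rcd <- raup_crick_bray(disj, n_null = 99, seed = 7)
  expect_gt(rcd["a", "b"], 0.95)
  expect_identical(raup_crick_bray(m, n_null = 49, seed = 8),
                   raup_crick_bray(m, n_null = 49, seed = 8))
})

test_that("classify_processes reproduces the five-way rule incl. boundaries", {
  grid <- expand.grid(b = c(-3, -2.01, -2, -1, 0, 1, 2, 2.01, 3),
                      r = c(-1, -0.96, -0.95, -0.5, 0, 0.5, 0.95,
                            0.96, 1))
  exp_rule <- function(b, r) {
    if (b > 2) "heterogeneous_selection"
    else if (b < -2) "homogeneous_selection"
    else if (r > 0.95) "dispersal_limitation"
    else if (r < -0.95) "homogenizing_dispersal"
    else "undominated"
  }
  n <- nrow(grid)
  ids <- paste0("P", seq_len(n + 1))
  bm <- rm <- matrix(0, n + 1, n + 1, dimnames = list(ids, ids))
  bm[1, -1] <- grid$b; rm[1, -1] <- grid$r
  bm[-1, 1] <- grid$b; rm[-1, 1] <- grid$r
  cls <- classify_processes(bm, rm)
  got <- cls[cls$sample_j == "P1", ]
  got <- got[order(match(got$sample_i, ids)), ]
  expect_equal(as.character(got$process),
               mapply(exp_rule, grid$b, grid$r))
  # totality: exactly one label per pair
  expect_false(anyNA(cls$process))
})

test_that("process_fractions sums to one per stratum and respects strata", {
  ids <- paste0("S", 1:6)
  b <- matrix(3, 6, 6, dimnames = list(ids, ids)); diag(b) <- 0
  r <- matrix(0, 6, 6, dimnames = list(ids, ids))
  cls <- classify_processes(b, r)
  fr <- process_fractions(cls)
  expect_equal(fr$heterogeneous_selection, 1)
  expect_equal(fr$deterministic, 1)
  expect_equal(sum(fr[, riversed:::PROCESS_LEVELS]), 1)
  strata <- setNames(rep(c("spring", "autumn"), each = 3), ids)
  fr2 <- process_fractions(cls, strata)
  expect_equal(nrow(fr2), 2)
  expect_equal(fr2$n_pairs, c(3, 3))
  expect_true(all(abs(rowSums(fr2[, riversed:::PROCESS_LEVELS]) - 1)
                  < 1e-9))
  # NA betaNTI pairs are excluded and counted
  b[1, 2] <- b[2, 1] <- NA
  cls2 <- classify_processes(b, r)
  expect_equal(attr(cls2, "n_excluded"), 1)
})
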