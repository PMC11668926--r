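# spatial_patterns: distance-decay and ANOSIM

test_that("distance_decay recovers planted slopes and exact p-values", {
  # construct similarity exactly linear in separation
  x <- setNames(c(0, 100, 300, 600, 1000), paste0("S", 1:5))
  g <- abs(outer(x, x, "-"))
  s <- 0.9 - 2e-4 * g          # planted slope -2e-4 per km
  beta <- 1 - s
  diag(beta) <- 0
  fit <- distance_decay(beta, x, n_perm = 99, seed = 1)
  expect_equal(fit$slope, -2e-4, tolerance = 1e-10)
  expect_equal(fit$slope_per_1000km, -0.2, tolerance = 1e-7)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$n_pairs, 10)
  # constant similarity -> slope 0
  b0 <- matrix(0.4, 5, 5, dimnames = list(names(x), names(x)))
  diag(b0) <- 0
  f0 <- distance_decay(1 - (1 - b0), x, n_perm = 19, seed = 1)
  expect_equal(f0$slope, 0, tolerance = 1e-12)
  # n = 4: exact enumeration over 24 relabelings equals sampled-oracle
  set.seed(2)
  x4 <- setNames(c(0, 50, 120, 400), paste0("S", 1:4))
  b4 <- random_dist(4, seed = 3, ids = names(x4))
  ex <- distance_decay(b4, x4, exact = TRUE)
  # independent enumeration
  s4 <- 1 - b4[lower.tri(b4)]
  slope_of <- function(perm) {
    gp <- abs(outer(x4[perm], x4[perm], "-"))[lower.tri(b4)]
    cov(gp, s4) / var(gp)
  }
  slopes <- apply(perms_oracle(4), 1, slope_of)
  obs <- slope_of(1:4)
  expect_equal(ex$p_value,
               mean(abs(slopes) >= abs(obs) - 1e-12))
  expect_equal(ex$n_permutations, 24)
  expect_error(distance_decay(b4, setNames(rep(5, 4), names(x4))),
               "constant")
})

test_that("decay slope flips sign when similarity is replaced by dissimilarity", {
  x <- setNames(seq(0, 800, length.out = 6), paste0("S", 1:6))
  b <- random_dist(6, seed = 4, ids = names(x))
  b <- b / max(b)
  f1 <- distance_decay(b, x, n_perm = 9, seed = 1)
  # feeding 1 - d as if it were a dissimilarity flips the regression
  f2 <- distance_decay(1 - b, x, n_perm = 9, seed = 1)
  # note: distance_decay(1-b) regresses 1-(1-d)=d, so slopes negate
  expect_equal(f1$slope, -f2$slope, tolerance = 1e-12)
})

test_that("anosim: extremes, exact enumeration and rank invariance", {
  ids <- paste0("S", 1:6)
  g <- c("a", "a", "a", "b", "b", "b")
  # every between-pair larger than every within-pair -> R = 1
  d <- matrix(0, 6, 6, dimnames = list(ids, ids))
  within <- outer(g, g, "==")
  d[within] <- runif(sum(within), 0.1, 0.2)
  d[!within] <- runif(sum(!within), 0.8, 0.9)
  d[lower.tri(d)] <- t(d)[lower.tri(d)]
  diag(d) <- 0
  a1 <- anosim(d, g, n_perm = 99, seed = 1)
  expect_equal(a1$r_statistic, 1)
  expect_lte(a1$p_value, 1)
  expect_gte(a1$p_value, 1 / 100)
  # monotone transform leaves R unchanged (rank-based)
  a2 <- anosim(sqrt(d), g, n_perm = 99, seed = 1)
  expect_equal(a2$r_statistic, a1$r_statistic)
  # agreement with vegan on a random instance
  dr <- random_dist(8, seed = 6)
  gr <- rep(c("u", "v"), each = 4)
  av <- vegan::anosim(as.dist(dr), gr, permutations = 9)
  am <- anosim(dr, gr, n_perm = 9, seed = 2)
  expect_equal(am$r_statistic, unname(av$statistic), tolerance = 1e-12)
  # exact p for 2+2 matches enumeration over label orderings
  d4 <- random_dist(4, seed = 7)
  g4 <- c("a", "a", "b", "b")
  ex <- anosim(d4, g4, exact = TRUE)
  stats_all <- apply(perms_oracle(4), 1, function(p)
    anosim_oracle_stat(d4, g4[p]))
  obs <- anosim_oracle_stat(d4, g4)
  expect_equal(ex$p_value, mean(stats_all >= obs - 1e-12))
  # degenerate groupings
  expect_error(anosim(d4, rep("a", 4)), "two groups")
  expect_warning(anosim(d, c(g[1:5], "c"), n_perm = 9, seed = 1),
                 "singleton")
})

test_that("pairwise_anosim returns one cell per group pair", {
  d <- random_dist(9, seed = 8)
  g <- rep(c("x", "y", "z"), each = 3)
  names(g) <- rownames(d)
  pw <- pairwise_anosim(d, g, n_perm = 49, seed = 1)
  expect_equal(nrow(pw), 3)
  expect_false(anyNA(pw$r_statistic))
  # planted separation: make z far from x and y
  d2 <- d
  far <- outer(g == "z", g == "z", "!=")
  d2[far] <- d2[far] + 10
  d2[lower.tri(d2)] <- t(d2)[lower.tri(d2)]
  pw2 <- pairwise_anosim(d2, g, n_perm = 49, seed = 1)
  zrows <- pw2$group2 == "z" | pw2$group1 == "z"
  expect_true(min(pw2$r_statistic[zrows]) >=
                max(pw2$r_statistic[!zrows]))
  # pair with < 2 samples per side -> NA cell
  g3 <- g; g3[g3 == "z"] <- c("z", "w", "w")
  pw3 <- suppressWarnings(pairwise_anosim(d, g3, n_perm = 9, seed = 1))
  expect_true(any(is.na(pw3$r_statistic)))
})

test_that("labels independent of distances give R centred on 0", {
  set.seed(10)
  rs <- replicate(60, {
    d <- random_dist(8, seed = sample.int(1e6, 1))
    anosim(d, sample(rep(c("a", "b"), each = 4)), n_perm = 1,
           seed = 1)$r_statistic
  })
  expect_lt(abs(mean(rs)), 0.1)
})
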