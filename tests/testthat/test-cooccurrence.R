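# cooccurrence: network construction, nulls, fits, keystones, O/R

test_that("prevalence_filter applies the detection-rate rule", {
  m <- matrix(0L, 48, 3, dimnames = list(paste0("s", 1:48),
                                         c("keep", "drop", "all")))
  m[1:10, "keep"] <- 1L    # 10/48 = 20.8%
  m[1:9, "drop"] <- 1L     # 18.75%
  m[, "all"] <- 2L
  f <- prevalence_filter(m, 0.20)
  expect_setequal(colnames(f), c("keep", "all"))
  expect_identical(prevalence_filter(m, 0), m)
})

test_that("spearman edges: hand rho, threshold enforcement, signed rule", {
  a <- c(1, 2, 3, 4, 5)
  b <- c(2, 1, 4, 3, 5)
  m <- cbind(A = a, B = b, C = rev(a), D = a * 2)
  rownames(m) <- paste0("s", 1:5)
  g <- spearman_edges(m, rho_min = 0.75, alpha = 0.2)
  el <- igraph::as_data_frame(g)
  ab <- el[(el$from == "A" & el$to == "B") |
             (el$from == "B" & el$to == "A"), ]
  expect_equal(ab$rho, 0.8)                      # 1 - 6*4/(5*24)
  # C is perfectly anti-correlated with A: excluded under signed rule
  expect_false(any((el$from == "C" | el$to == "C") &
                     (el$from == "A" | el$to == "A")))
  gabs <- spearman_edges(m, rho_min = 0.75, alpha = 0.2,
                         absolute = TRUE)
  elabs <- igraph::as_data_frame(gabs)
  expect_true(any((elabs$from %in% c("A", "C")) &
                    (elabs$to %in% c("A", "C"))))
  # every retained edge re-tests above threshold
  n <- nrow(m)
  for (k in seq_len(nrow(el))) {
    r <- cor(m[, el$from[k]], m[, el$to[k]], method = "spearman")
    expect_gt(r, 0.75)
    tt <- r * sqrt((n - 2) / (1 - r^2))
    expect_lt(2 * pt(-abs(tt), n - 2), 0.2)
  }
  expect_error(spearman_edges(m[1:3, ]), "4 samples")
  mz <- cbind(m, Z = rep(3, 5))
  expect_warning(spearman_edges(mz, 0.75, 0.1), "zero-variance")
})

test_that("topology: path/star/complete and brute-force betweenness", {
  path <- igraph::make_graph(~ A - B - C)
  tp <- topology(path)
  expect_equal(tp$betweenness[tp$node == "B"], 1)
  expect_equal(tp$betweenness[tp$node == "A"], 0)
  expect_equal(tp$closeness[tp$node == "B"], 1)
  star <- igraph::make_star(7, mode = "undirected")
  expect_equal(max(topology(star)$degree), 6)
  cmpl <- igraph::make_full_graph(5)
  expect_true(all(topology(cmpl)$betweenness == 0))
  for (seed in 1:4) {
    set.seed(seed)
    g <- igraph::sample_gnp(10, 0.35)
    igraph::V(g)$name <- paste0("n", 1:10)
    tp2 <- topology(g)
    expect_equal(tp2$betweenness, betweenness_oracle(g),
                 tolerance = 1e-9)
    expect_equal(tp2$degree, unname(igraph::degree(g)))
  }
  lonely <- igraph::make_graph(~ A - B) + igraph::vertices("C")
  expect_equal(topology(lonely)$closeness[3], 0)
})

test_that("ER ensemble: handshake lemma, mean degree, determinism", {
  ens <- er_null_ensemble(30, 80, reps = 5, seed = 11)
  expect_length(ens, 5)
  for (g in ens) {
    expect_equal(sum(igraph::degree(g)), 160)
    expect_equal(igraph::ecount(g), 80)
    expect_false(any(igraph::which_loop(g)))
  }
  ens2 <- er_null_ensemble(30, 80, reps = 5, seed = 11)
  expect_identical(lapply(ens, igraph::as_edgelist),
                   lapply(ens2, igraph::as_edgelist))
  expect_error(er_null_ensemble(5, 11), "maximum")
  # mean degree arithmetic at the published network size
  g1 <- er_null_ensemble(1212, 20655, reps = 1, seed = 1)[[1]]
  expect_equal(mean(igraph::degree(g1)), 2 * 20655 / 1212)
})

test_that("degree-distribution fits recover exact models", {
  # frequencies exactly on a power law: adj R^2 = 1
  k <- c(1, 2, 4, 8, 16)
  f <- 1024 * k^-2                       # 1024 256 64 16 4, exact
  fit <- fit_degree_distribution(rep(k, f), "power_law")
  expect_equal(fit$adjusted_r_squared, 1, tolerance = 1e-9)
  expect_equal(unname(fit$parameters["exponent"]), -2,
               tolerance = 1e-9)
  # frequencies exactly Gaussian on the integer grid (spectrum input)
  k2 <- 1:40
  f2 <- 500 * exp(-(k2 - 20)^2 / (2 * 16))
  fitg <- fit_degree_distribution(
    data.frame(degree = k2, frequency = f2), "gaussian")
  expect_equal(fitg$adjusted_r_squared, 1, tolerance = 1e-9)
  expect_equal(unname(fitg$parameters["mu"]), 20, tolerance = 1e-6)
  # rounded integer counts still fit nearly perfectly
  fitr <- fit_degree_distribution(rep(k2, round(f2)), "gaussian")
  expect_gt(fitr$adjusted_r_squared, 0.999)
  expect_error(fit_degree_distribution(rep(1, 5), "power_law"),
               ">= 10 nodes")
})

test_that("keystone rule is a strict double threshold", {
  topo <- data.frame(node = c("a", "b", "c", "d"),
                     degree = c(150, 90, 150, 101),
                     betweenness = c(1000, 10, 6000, 4999))
  expect_setequal(keystones(topo), c("a", "d"))
})

test_that("O/R ratios: edge conservation and identity-label case", {
  set.seed(21)
  g <- igraph::sample_gnm(40, 120)
  igraph::V(g)$name <- paste0("n", 1:40)
  grp <- setNames(rep(c("p1", "p2", "p3"), length.out = 40),
                  igraph::V(g)$name)
  orr <- o_r_ratios(g, grp, reps = 60, seed = 3)
  expect_equal(sum(orr$observed), igraph::ecount(g))
  expect_equal(sum(orr$o_percent), 100)
  expect_true(all(orr$o_r_ratio >= 0))
  # all labels identical: ratio 1 by edge-count conservation
  one <- setNames(rep("all", 40), igraph::V(g)$name)
  orr1 <- o_r_ratios(g, one, reps = 10, seed = 4)
  expect_equal(nrow(orr1), 1)
  expect_equal(orr1$o_r_ratio, 1)
  expect_equal(orr1$observed, 120)
  # ensemble route agrees with streaming route
  ens <- er_null_ensemble(40, 120, reps = 60, seed = 3)
  orr2 <- o_r_ratios(g, grp, ensemble = ens)
  expect_equal(orr2$observed, orr$observed)
  expect_equal(sum(orr2$observed), 120)
})

test_that("an ER graph shows no scale-free contrast (fit ranking flips)", {
  set.seed(31)
  er <- igraph::sample_gnm(600, 6000)
  pw <- fit_degree_distribution(er, "power_law")
  ga <- fit_degree_distribution(er, "gaussian")
  expect_gt(ga$adjusted_r_squared, pw$adjusted_r_squared)
  # scale-free-ish graph: preferential attachment
  ba <- igraph::sample_pa(600, m = 10, directed = FALSE)
  pw2 <- fit_degree_distribution(ba, "power_law")
  ga2 <- fit_degree_distribution(ba, "gaussian")
  expect_gt(pw2$adjusted_r_squared, ga2$adjusted_r_squared)
})
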