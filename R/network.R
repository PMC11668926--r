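# cooccurrence: thresholded Spearman networks, Erdos-Renyi nulls,
# degree-distribution fits, keystone selection and O/R co-existence
# ratios. Graphs are igraph objects throughout.

#' Prevalence filter
#'
#' Keeps ASVs detected (count > 0) in at least `min_detection` of
#' samples — the standard pre-filter before correlation networks.
#'
#' @param counts Count matrix (samples x ASVs).
#' @param min_detection Minimum detection rate (default 0.20).
#' @return Column-subset count matrix.
#' @export
prevalence_filter <- function(counts, min_detection = 0.20) {
  counts <- validate_asv_table(counts)
  keep <- colMeans(counts > 0) >= min_detection
  counts[, keep, drop = FALSE]
}

#' Build a Spearman co-occurrence network
#'
#' Pairwise Spearman correlations (average-rank ties) across samples;
#' p-values from the t approximation on `n - 2` df. An edge is kept iff
#' `rho > rho_min` and `p < alpha` (positive co-occurrence only;
#' `absolute = TRUE` admits `|rho| > rho_min`).
#'
#' @param counts Count matrix (samples x ASVs), usually
#'   prevalence-filtered.
#' @param rho_min Correlation threshold (default 0.8).
#' @param alpha Significance threshold on raw p (default 0.01).
#' @param absolute Use `|rho|` instead of signed rho.
#' @param adjust_p Apply Benjamini-Hochberg across all pairs before
#'   thresholding (off by default: raw p, matching common practice).
#' @param keep_isolated Keep nodes without any retained edge (default
#'   `FALSE`: the network consists of connected ASVs only).
#' @return An [igraph::graph] with edge attributes `rho` and `p` and
#'   vertex attribute `name`.
#' @export
spearman_edges <- function(counts, rho_min = 0.8, alpha = 0.01,
                           absolute = FALSE, adjust_p = FALSE,
                           keep_isolated = FALSE) {
  counts <- validate_asv_table(counts)
  n <- nrow(counts)
  if (n < 4) stop("need at least 4 samples", call. = FALSE)
  v <- apply(counts, 2, var)
  if (any(v == 0)) {
    warning("excluding ", sum(v == 0), " zero-variance ASV(s)")
    counts <- counts[, v > 0, drop = FALSE]
  }
  rho <- cor(counts, method = "spearman")
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[abs(rho) >= 1 - 1e-12] <- 0
  ut <- upper.tri(rho)
  if (adjust_p) p[ut] <- stats::p.adjust(p[ut], method = "BH")
  score <- if (absolute) abs(rho) else rho
  keep <- ut & score > rho_min & p < alpha
  idx <- which(keep, arr.ind = TRUE)
  edges <- data.frame(from = colnames(counts)[idx[, 1]],
                      to = colnames(counts)[idx[, 2]],
                      rho = rho[keep], p = p[keep],
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = colnames(counts)))
  if (!keep_isolated)
    g <- igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
  g
}

#' Node-level topology
#'
#' Degree, exact unnormalised shortest-path betweenness (edges
#' unweighted) and closeness normalised within each connected component
#' (`(nc - 1) / sum of distances`; isolated nodes score 0).
#'
#' @param graph An igraph graph.
#' @return Data frame: `node`, `degree`, `betweenness`, `closeness`.
#' @export
topology <- function(graph) {
  deg <- igraph::degree(graph)
  btw <- igraph::betweenness(graph, directed = FALSE, weights = NA,
                             normalized = FALSE)
  comp <- igraph::components(graph)
  clo <- numeric(length(deg))
  dmat <- igraph::distances(graph, weights = NA)
  for (k in seq_len(comp$no)) {
    memb <- which(comp$membership == k)
    nc <- length(memb)
    if (nc < 2) { clo[memb] <- 0; next }
    clo[memb] <- (nc - 1) / rowSums(dmat[memb, memb, drop = FALSE])
  }
  data.frame(node = igraph::V(graph)$name %||% as.character(seq_along(deg)),
             degree = unname(deg), betweenness = unname(btw),
             closeness = clo, stringsAsFactors = FALSE)
}

#' Erdos-Renyi G(n, m) null ensemble
#'
#' Uniform simple graphs with exactly the observed node and edge counts,
#' the customary null for co-occurrence network non-randomness.
#'
#' @param n_nodes,n_edges Node and edge counts to match.
#' @param reps Ensemble size (the classical protocol uses 10,000; keep
#'   memory in mind for large graphs — each replicate is materialised).
#' @param seed Optional seed.
#' @return List of igraph graphs.
#' @export
er_null_ensemble <- function(n_nodes, n_edges, reps = 10000, seed = NULL) {
  if (n_edges > n_nodes * (n_nodes - 1) / 2)
    stop("n_edges exceeds the simple-graph maximum", call. = FALSE)
  with_seed(seed, lapply(seq_len(reps), function(i)
    igraph::sample_gnm(n_nodes, n_edges)))
}

#' Fit a power-law or Gaussian model to a degree distribution
#'
#' Power law: OLS of `log10(frequency)` on `log10(degree)` over observed
#' positive-frequency, positive degrees. Gaussian:
#' `a exp(-(k - mu)^2 / (2 sigma^2))` least-squares fit to the
#' integer-degree frequency spectrum over the full observed degree range
#' (zero-frequency integers included, no rebinning).
#'
#' @param graph An igraph graph, a numeric vector of node degrees, or a
#'   data frame with columns `degree` and `frequency` (a pre-tabulated
#'   spectrum).
#' @param model `"power_law"` or `"gaussian"`.
#' @return Object of class `degree_fit`: model, parameters, r_squared,
#'   adjusted_r_squared, and the fitted spectrum.
#' @export
fit_degree_distribution <- function(graph, model = c("power_law",
                                                     "gaussian")) {
  model <- match.arg(model)
  if (is.data.frame(graph)) {
    stopifnot(all(c("degree", "frequency") %in% names(graph)))
    k_all <- graph$degree
    f_all <- graph$frequency
    if (sum(f_all[k_all >= 1]) < 10)
      stop("need >= 10 nodes with degree >= 1", call. = FALSE)
  } else {
    deg <- if (is.numeric(graph)) graph else igraph::degree(graph)
    if (sum(deg >= 1) < 10)
      stop("need >= 10 nodes with degree >= 1", call. = FALSE)
    tab <- table(factor(deg, levels = min(deg):max(deg)))
    k_all <- as.integer(names(tab))
    f_all <- as.numeric(tab)
  }
  if (model == "power_law") {
    sel <- k_all >= 1 & f_all > 0
    k <- k_all[sel]; f <- f_all[sel]
    if (length(k) < 3) stop("too few points for a power-law fit",
                            call. = FALSE)
    fit <- lm(log10(f) ~ log10(k))
    pred <- fitted(fit)
    r2 <- 1 - sum((log10(f) - pred)^2) / sum((log10(f) - mean(log10(f)))^2)
    n <- length(k); npar <- 2
    pars <- c(exponent = unname(coef(fit)[2]),
              log10_c = unname(coef(fit)[1]))
    spectrum <- data.frame(degree = k, frequency = f,
                           fitted = 10^pred)
  } else {
    k <- k_all; f <- f_all
    if (length(k) < 4) stop("too few points for a Gaussian fit",
                            call. = FALSE)
    w <- f / sum(f)
    start <- list(a = max(f), mu = sum(w * k),
                  sigma = max(sqrt(sum(w * (k - sum(w * k))^2)), 0.5))
    fml <- f ~ a * exp(-(k - mu)^2 / (2 * sigma^2))
    fit <- tryCatch(
      suppressWarnings(
        nls(fml, data = data.frame(k = k, f = f), start = start,
            control = nls.control(maxiter = 200, warnOnly = TRUE))),
      error = function(e) NULL)
    if (is.null(fit)) {
      sse_fun <- function(p)
        sum((f - p[1] * exp(-(k - p[2])^2 / (2 * p[3]^2)))^2)
      op <- optim(unlist(start), sse_fun)
      pars <- c(a = op$par[[1]], mu = op$par[[2]], sigma = abs(op$par[[3]]))
      pred <- pars[["a"]] * exp(-(k - pars[["mu"]])^2 / (2 * pars[["sigma"]]^2))
    } else {
      pars <- coef(fit)
      pars[["sigma"]] <- abs(pars[["sigma"]])
      pred <- fitted(fit)
    }
    r2 <- 1 - sum((f - pred)^2) / sum((f - mean(f))^2)
    n <- length(k); npar <- 3
    spectrum <- data.frame(degree = k, frequency = f, fitted = pred)
  }
  adj <- 1 - (1 - r2) * (n - 1) / (n - npar - 1)
  out <- list(model = model, parameters = pars, r_squared = r2,
              adjusted_r_squared = adj, n_points = n,
              spectrum = spectrum)
  class(out) <- "degree_fit"
  out
}

#' @export
print.degree_fit <- function(x, ...) {
  cat(sprintf("%s fit over %d degree bins: adj. R^2 = %.4f\n",
              x$model, x$n_points, x$adjusted_r_squared))
  invisible(x)
}

#' Keystone node selection
#'
#' High-connectivity, low-betweenness nodes: `degree > degree_min` and
#' `betweenness < betweenness_max` (raw path counts).
#'
#' @param topo Data frame from [topology()].
#' @param degree_min Degree threshold (default 100).
#' @param betweenness_max Betweenness threshold (default 5000).
#' @return Character vector of keystone node ids.
#' @export
keystones <- function(topo, degree_min = 100, betweenness_max = 5000) {
  topo$node[topo$degree > degree_min & topo$betweenness < betweenness_max]
}

# Count edges per unordered label pair. `labels` is a named vector over
# the node ids used by the graph's edge list.
count_pair_edges <- function(ends_mat, labels, pair_levels) {
  l1 <- labels[ends_mat[, 1]]
  l2 <- labels[ends_mat[, 2]]
  key <- ifelse(l1 <= l2, paste(l1, l2, sep = "\r"),
                paste(l2, l1, sep = "\r"))
  table(factor(key, levels = pair_levels))
}

#' Observed vs random co-existence (O/R) ratios between node groups
#'
#' For every unordered pair of node labels (including within-group
#' pairs): `O` = observed edge count, `R` = mean edge count between the
#' same labelled node sets across an Erdos-Renyi G(n, m) ensemble with
#' labels fixed to nodes, `O%` = share of all observed edges, and the
#' ratio `O/R` (> 1 means more co-existence than chance).
#'
#' @param graph The observed igraph network.
#' @param groups Named character vector mapping every node id to a label
#'   (e.g. phylum or abundance category).
#' @param ensemble Optional ensemble from [er_null_ensemble()]; when
#'   `NULL`, `reps` replicates are streamed internally without being
#'   kept in memory.
#' @param reps Replicates when streaming (default 999).
#' @param seed Optional seed (streaming mode).
#' @return Data frame: `group1`, `group2`, `observed`, `expected`,
#'   `o_percent`, `o_r_ratio` (0 when O = 0; `Inf` when R = 0 < O).
#' @export
o_r_ratios <- function(graph, groups, ensemble = NULL, reps = 999,
                       seed = NULL) {
  nodes <- igraph::V(graph)$name
  if (!all(nodes %in% names(groups)))
    stop("every node needs a group label", call. = FALSE)
  labels <- groups[nodes]
  lv <- sort(unique(labels))
  pairs <- cbind(lv, lv)
  if (length(lv) > 1) pairs <- rbind(pairs, t(utils::combn(lv, 2)))
  pair_levels <- paste(pairs[, 1], pairs[, 2], sep = "\r")
  em <- igraph::as_edgelist(graph, names = TRUE)
  obs <- count_pair_edges(em, labels, pair_levels)
  n <- length(nodes)
  m <- igraph::ecount(graph)
  idx_labels <- setNames(labels, as.character(seq_len(n)))
  sum_null <- numeric(length(pair_levels))
  count_rep <- function(g) {
    e <- igraph::as_edgelist(g, names = FALSE)
    storage.mode(e) <- "character"
    count_pair_edges(e, idx_labels, pair_levels)
  }
  if (is.null(ensemble)) {
    with_seed(seed, for (r in seq_len(reps)) {
      sum_null <- sum_null + count_rep(igraph::sample_gnm(n, m))
    })
    nrep <- reps
  } else {
    for (g in ensemble) sum_null <- sum_null + count_rep(g)
    nrep <- length(ensemble)
  }
  expected <- as.numeric(sum_null) / nrep
  O <- as.numeric(obs)
  ratio <- ifelse(O == 0, 0, ifelse(expected == 0, Inf, O / expected))
  data.frame(group1 = pairs[, 1], group2 = pairs[, 2],
             observed = O, expected = expected,
             o_percent = 100 * O / max(m, 1),
             o_r_ratio = ratio, stringsAsFactors = FALSE)
}
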