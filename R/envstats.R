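# env_stats: Mantel and partial Mantel tests, environmental distances,
# two-set variance partitioning via redundancy analysis, and the rank
# tests used for group contrasts.

mantel_r <- function(v1, v2, method) {
  if (method == "spearman") cor(rank(v1), rank(v2)) else cor(v1, v2)
}

#' Mantel test between two distance matrices
#'
#' Correlation (Spearman by default) of the unfolded off-diagonal
#' vectors; significance from permuting rows/columns of `dm2`.
#' One-sided (`r_perm >= r_obs`), add-one rule.
#'
#' @param dm1,dm2 Distance matrices sharing sample ids.
#' @param method `"spearman"` or `"pearson"`.
#' @param n_perm Permutations (default 9999).
#' @param seed Optional seed.
#' @param exact Enumerate all `n!` permutations (tiny n).
#' @return Object of class `mantel_result`: `r`, `p_value`,
#'   `n_permutations`, `method`, `controlled` (`NA` here).
#' @export
mantel <- function(dm1, dm2, method = c("spearman", "pearson"),
                   n_perm = 9999, seed = NULL, exact = FALSE) {
  method <- match.arg(method)
  al <- align_dist(dm1, dm2)
  d1 <- al[[1]]; d2 <- al[[2]]
  n <- nrow(d1)
  if (n < 4) stop("need >= 4 samples", call. = FALSE)
  v1 <- lower_vec(d1)
  if (sd(v1) == 0 || sd(lower_vec(d2)) == 0)
    stop("constant distance matrix: Mantel r undefined", call. = FALSE)
  r_obs <- mantel_r(v1, lower_vec(d2), method)
  stat <- function(perm) mantel_r(v1, lower_vec(d2[perm, perm]), method)
  if (exact) {
    rs <- apply(all_permutations(n), 1, stat)
    p <- mean(rs >= r_obs - 1e-12)
    nper <- factorial(n)
  } else {
    rs <- with_seed(seed, replicate(n_perm, stat(sample.int(n))))
    p <- (1 + sum(rs >= r_obs - 1e-12)) / (n_perm + 1)
    nper <- n_perm
  }
  out <- list(r = r_obs, p_value = p, n_permutations = nper,
              method = method, controlled = NA_character_)
  class(out) <- "mantel_result"
  out
}

#' @export
print.mantel_result <- function(x, ...) {
  ctl <- if (is.na(x$controlled)) "" else paste0(" | ", x$controlled)
  cat(sprintf("Mantel r = %.4f%s (%s, p = %.4g, %d permutations)\n",
              x$r, ctl, x$method, x$p_value, x$n_permutations))
  invisible(x)
}

partial_r <- function(rab, rac, rbc) {
  (rab - rac * rbc) / sqrt((1 - rac^2) * (1 - rbc^2))
}

#' Partial Mantel test
#'
#' First-order partial correlation `r_AB.C` between `dmA` and `dmB`
#' controlling for `dmC` (typically geographic distance), with
#' significance from permuting `dmB` and recomputing the partial
#' statistic.
#'
#' @param dmA,dmB,dmC Distance matrices sharing ids.
#' @inheritParams mantel
#' @return A `mantel_result` with `controlled` set.
#' @export
partial_mantel <- function(dmA, dmB, dmC,
                           method = c("spearman", "pearson"),
                           n_perm = 9999, seed = NULL, exact = FALSE) {
  method <- match.arg(method)
  al <- align_dist(dmA, dmB, dmC)
  vA <- lower_vec(al[[1]]); dB <- al[[2]]; vC <- lower_vec(al[[3]])
  n <- nrow(dB)
  if (method == "spearman") { vA <- rank(vA); vC <- rank(vC) }
  unfold <- function(d) {
    v <- lower_vec(d)
    if (method == "spearman") rank(v) else v
  }
  vB <- unfold(dB)
  rac <- cor(vA, vC)
  rbc <- cor(vB, vC)
  if (abs(rac) >= 1 - 1e-12 || abs(rbc) >= 1 - 1e-12)
    stop("control matrix is collinear with an input", call. = FALSE)
  r_obs <- partial_r(cor(vA, vB), rac, rbc)
  stat <- function(perm) {
    vBp <- unfold(dB[perm, perm])
    rbcp <- cor(vBp, vC)
    if (abs(rbcp) >= 1 - 1e-12) return(NA_real_)
    partial_r(cor(vA, vBp), rac, rbcp)
  }
  if (exact) {
    rs <- apply(all_permutations(n), 1, stat)
    p <- mean(rs >= r_obs - 1e-12, na.rm = TRUE)
    nper <- factorial(n)
  } else {
    rs <- with_seed(seed, replicate(n_perm, stat(sample.int(n))))
    p <- (1 + sum(rs >= r_obs - 1e-12, na.rm = TRUE)) / (n_perm + 1)
    nper <- n_perm
  }
  out <- list(r = r_obs, p_value = p, n_permutations = nper,
              method = method, controlled = deparse(substitute(dmC)))
  class(out) <- "mantel_result"
  out
}

#' Environmental distance matrix for one factor
#'
#' Absolute differences on the z-scored factor, so the matrix is
#' invariant to affine transforms of the measurement scale.
#'
#' @param meta Metadata data frame (sample ids as rownames) or a named
#'   numeric vector.
#' @param factor_name Column to use when `meta` is a data frame.
#' @return Symmetric distance matrix with sample ids.
#' @export
env_distance <- function(meta, factor_name = NULL) {
  if (is.data.frame(meta)) {
    stopifnot(!is.null(factor_name), factor_name %in% names(meta))
    z <- setNames(meta[[factor_name]], rownames(meta))
  } else z <- meta
  if (!is.numeric(z)) stop("factor must be numeric", call. = FALSE)
  s <- sd(z)
  if (s == 0) {
    warning("constant factor: environmental distances are all zero")
    zs <- z * 0
  } else zs <- (z - mean(z)) / s
  d <- abs(outer(zs, zs, "-"))
  dimnames(d) <- list(names(z), names(z))
  d
}

# Redundancy-analysis R2: share of total variance of (centred) Y
# explained by the fitted values of the multivariate regression on X.
rda_r2 <- function(Y, X) {
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  if (is.null(X) || ncol(X) == 0) return(0)
  qrx <- qr(cbind(`(Intercept)` = 1, X))
  if (qrx$rank < ncol(X) + 1) {
    dropped <- qrx$pivot[-seq_len(qrx$rank)] - 1L
    stop("rank-deficient predictor set; collinear columns: ",
         paste(colnames(X)[dropped], collapse = ", "), call. = FALSE)
  }
  fit <- qr.fitted(qrx, Yc)
  sum(fit^2) / sum(Yc^2)
}

ezekiel <- function(r2, n, m) 1 - (1 - r2) * (n - 1) / (n - m - 1)

#' Two-set variance partitioning (RDA-based)
#'
#' Partitions the variance of the Hellinger-transformed community table
#' between two predictor sets (e.g. natural vs nutrient factors) using
#' redundancy-analysis R-squared converted to adjusted R-squared by
#' Ezekiel's formula. Fractions: `a` pure set1, `b` shared, `c` pure
#' set2, `d` residual; raw values sum to 1 exactly, reported fractions
#' truncate negatives to 0.
#'
#' @param counts Community count matrix (samples x taxa).
#' @param set1,set2 Numeric predictor matrices / data frames over the
#'   same samples (standardised internally).
#' @param hellinger Apply the Hellinger transform (default `TRUE`).
#' @return Object of class `vpa_result` with `fractions` (truncated)
#'   and `raw`.
#' @export
vpa_two_sets <- function(counts, set1, set2, hellinger = TRUE) {
  Y <- as.matrix(counts)
  if (hellinger) Y <- sqrt(sweep(Y, 1, pmax(rowSums(Y), 1e-300), "/"))
  std <- function(X) {
    if (is.null(X)) return(NULL)
    X <- as.matrix(X)
    if (ncol(X) == 0) return(NULL)
    scale(X)
  }
  X1 <- std(set1); X2 <- std(set2)
  m1 <- if (is.null(X1)) 0 else ncol(X1)
  m2 <- if (is.null(X2)) 0 else ncol(X2)
  n <- nrow(Y)
  if (n <= m1 + m2 + 1)
    stop("need more samples than total predictors + 1", call. = FALSE)
  adj1 <- ezekiel(rda_r2(Y, X1), n, m1)
  adj2 <- ezekiel(rda_r2(Y, X2), n, m2)
  adjU <- ezekiel(rda_r2(Y, cbind(X1, X2)), n, m1 + m2)
  raw <- c(a = adjU - adj2, b = adj1 + adj2 - adjU,
           c = adjU - adj1, d = 1 - adjU)
  out <- list(raw = raw, fractions = pmax(raw, 0),
              adj_set1 = adj1, adj_set2 = adj2, adj_union = adjU,
              n = n, m1 = m1, m2 = m2)
  class(out) <- "vpa_result"
  out
}

#' @export
print.vpa_result <- function(x, ...) {
  cat("Variance partitioning (adjusted R^2 shares):\n")
  print(round(x$fractions, 4))
  invisible(x)
}

#' Wilcoxon rank-sum test
#'
#' Average-rank ties; exact p by enumeration of all group assignments
#' when `n_x + n_y <= 12`, otherwise normal approximation with tie
#' correction (no continuity correction). The statistic is the rank sum
#' of `x`.
#'
#' @param x,y Numeric vectors.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return List with `statistic` (rank sum of x), `p_value`, `exact`.
#' @export
wilcoxon_rank_sum <- function(x, y, alternative = c("two.sided", "less",
                                                    "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) > 0, length(y) > 0)
  nx <- length(x); ny <- length(y); n <- nx + ny
  rk <- rank(c(x, y))
  w <- sum(rk[seq_len(nx)])
  if (n <= 12) {
    sets <- utils::combn(n, nx)
    ws <- colSums(matrix(rk[sets], nrow = nx))
    tolr <- 1e-9
    p_le <- mean(ws <= w + tolr)
    p_ge <- mean(ws >= w - tolr)
    p <- switch(alternative,
                less = p_le, greater = p_ge,
                two.sided = min(1, 2 * min(p_le, p_ge)))
    exact <- TRUE
  } else {
    mu <- nx * (n + 1) / 2
    ties <- table(rk)
    sig2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (w - mu) / sqrt(sig2)
    p <- switch(alternative,
                less = stats::pnorm(z),
                greater = stats::pnorm(z, lower.tail = FALSE),
                two.sided = 2 * stats::pnorm(-abs(z)))
    exact <- FALSE
  }
  list(statistic = w, p_value = p, exact = exact)
}

#' Kruskal-Wallis rank test
#'
#' H statistic with tie correction; p from the chi-square approximation
#' with `k - 1` degrees of freedom.
#'
#' @param groups List of numeric vectors (>= 2 nonempty groups).
#' @return List with `statistic` (H), `df`, `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2,
            all(lengths(groups) > 0))
  v <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  n <- length(v)
  rk <- rank(v)
  rbar <- tapply(rk, g, mean)
  ng <- lengths(groups)
  H <- 12 / (n * (n + 1)) * sum(ng * (rbar - (n + 1) / 2)^2)
  ties <- table(rk)
  C <- 1 - sum(ties^3 - ties) / (n^3 - n)
  H <- if (C > 0) H / C else 0
  df <- length(groups) - 1
  list(statistic = H, df = df,
       p_value = if (H == 0) 1 else pchisq(H, df, lower.tail = FALSE))
}
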