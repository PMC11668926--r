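# spatial_patterns: distance-decay regression and ANOSIM.

#' Distance-decay regression with permutation significance
#'
#' Regresses pairwise community similarity `1 - d_ij` on pairwise
#' along-river separation `|x_i - x_j|` (ordinary least squares). The
#' permutation p-value shuffles sample identities in the geographic
#' vector and is two-sided on `|slope|` with the add-one rule.
#'
#' @param beta Dissimilarity matrix with sample ids.
#' @param dist_to_mouth Named numeric vector of per-sample distance to
#'   the river mouth (km), or a metadata data frame carrying
#'   `dist_to_mouth_km` with sample ids as rownames.
#' @param n_perm Number of permutations (default 9999).
#' @param seed Optional seed.
#' @param exact Enumerate all `n!` relabelings instead of sampling
#'   (only for small n).
#' @return Object of class `decay_fit`: slope (per km), slope per
#'   1,000 km, intercept, r_squared, p_value, n_pairs.
#' @export
distance_decay <- function(beta, dist_to_mouth, n_perm = 9999,
                           seed = NULL, exact = FALSE) {
  beta <- check_dist_matrix(beta)
  if (is.data.frame(dist_to_mouth))
    dist_to_mouth <- setNames(dist_to_mouth$dist_to_mouth_km,
                              rownames(dist_to_mouth))
  ids <- rownames(beta)
  if (!all(ids %in% names(dist_to_mouth)))
    stop("dist_to_mouth does not cover all samples", call. = FALSE)
  x <- dist_to_mouth[ids]
  s <- 1 - lower_vec(beta)
  gsep <- function(xv) lower_vec(abs(outer(xv, xv, "-")))
  g <- gsep(x)
  if (sd(g) == 0) stop("geographic separations are constant", call. = FALSE)

  ols <- function(gv) {
    b <- cov(gv, s) / var(gv)
    c(slope = b, intercept = mean(s) - b * mean(gv))
  }
  fit <- ols(g)
  res <- s - (fit["intercept"] + fit["slope"] * g)
  r2 <- 1 - sum(res^2) / sum((s - mean(s))^2)

  n <- length(x)
  slope_stat <- function(perm) {
    gp <- gsep(x[perm])
    if (sd(gp) == 0) return(0)
    cov(gp, s) / var(gp)
  }
  if (exact) {
    perms <- all_permutations(n)
    stats_perm <- apply(perms, 1, slope_stat)
    p <- mean(abs(stats_perm) >= abs(fit["slope"]) - 1e-12)
  } else {
    stats_perm <- with_seed(seed, replicate(n_perm,
      slope_stat(sample.int(n))))
    p <- (1 + sum(abs(stats_perm) >= abs(fit["slope"]) - 1e-12)) /
      (n_perm + 1)
  }
  out <- list(slope = unname(fit["slope"]),
              slope_per_1000km = unname(fit["slope"]) * 1000,
              intercept = unname(fit["intercept"]),
              r_squared = r2, p_value = p,
              n_pairs = length(s),
              n_permutations = if (exact) factorial(n) else n_perm)
  class(out) <- "decay_fit"
  out
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "Distance-decay: slope %.4g /1000km (R^2 = %.3f, p = %.4g, %d pairs)\n",
    x$slope_per_1000km, x$r_squared, x$p_value, x$n_pairs))
  invisible(x)
}

# Core ANOSIM statistic: ranks of all pairwise dissimilarities, R =
# (mean between-group rank - mean within-group rank) / (n(n-1)/4).
anosim_stat <- function(rnk, within, denom) {
  (mean(rnk[!within]) - mean(rnk[within])) / denom
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of whether between-group dissimilarities
#' exceed within-group ones. p counts permutations with `R >= R_obs`,
#' including the observed labelling (add-one rule).
#'
#' @param beta Dissimilarity matrix with sample ids.
#' @param groups Group labels, named by sample or in matrix order.
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional seed.
#' @param exact Enumerate all label permutations (small n only).
#' @return Object of class `anosim_result` with `r_statistic`,
#'   `p_value`, `n_permutations`, `grouping`.
#' @export
anosim <- function(beta, groups, n_perm = 999, seed = NULL,
                   exact = FALSE) {
  beta <- check_dist_matrix(beta)
  ids <- rownames(beta)
  if (!is.null(names(groups))) groups <- groups[ids]
  groups <- as.character(groups)
  sizes <- table(groups)
  if (any(sizes < 2)) {
    drop <- names(sizes)[sizes < 2]
    warning("dropping singleton group(s): ", paste(drop, collapse = ", "))
    keep <- !(groups %in% drop)
    beta <- beta[keep, keep, drop = FALSE]
    groups <- groups[keep]
  }
  if (length(unique(groups)) < 2)
    stop("need at least two groups with >= 2 samples", call. = FALSE)
  n <- nrow(beta)
  rnk <- rank(lower_vec(beta))
  denom <- n * (n - 1) / 4
  within_of <- function(g) {
    same <- outer(g, g, "==")
    lower_vec(same)
  }
  r_obs <- anosim_stat(rnk, within_of(groups), denom)
  if (exact) {
    perms <- all_permutations(n)
    rs <- apply(perms, 1, function(p)
      anosim_stat(rnk, within_of(groups[p]), denom))
    p_val <- mean(rs >= r_obs - 1e-12)
    n_used <- nrow(perms)
  } else {
    rs <- with_seed(seed, replicate(n_perm,
      anosim_stat(rnk, within_of(sample(groups)), denom)))
    p_val <- (1 + sum(rs >= r_obs - 1e-12)) / (n_perm + 1)
    n_used <- n_perm
  }
  out <- list(r_statistic = r_obs, p_value = p_val,
              n_permutations = n_used,
              grouping = deparse(substitute(groups)))
  class(out) <- "anosim_result"
  out
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("ANOSIM R = %.4f (p = %.4g, %d permutations)\n",
              x$r_statistic, x$p_value, x$n_permutations))
  invisible(x)
}

#' Pairwise ANOSIM across all group pairs
#'
#' @inheritParams anosim
#' @return Data frame with one row per unordered group pair: `group1`,
#'   `group2`, `r_statistic`, `p_value`, `n1`, `n2`. Pairs with fewer
#'   than two samples on either side yield `NA`.
#' @export
pairwise_anosim <- function(beta, groups, n_perm = 999, seed = NULL) {
  beta <- check_dist_matrix(beta)
  ids <- rownames(beta)
  if (!is.null(names(groups))) groups <- groups[ids]
  groups <- as.character(groups)
  lv <- sort(unique(groups))
  prs <- utils::combn(lv, 2)
  out <- data.frame(group1 = prs[1, ], group2 = prs[2, ],
                    r_statistic = NA_real_, p_value = NA_real_,
                    n1 = NA_integer_, n2 = NA_integer_,
                    stringsAsFactors = FALSE)
  for (k in seq_len(ncol(prs))) {
    sel <- groups %in% prs[, k]
    g <- groups[sel]
    out$n1[k] <- sum(g == prs[1, k])
    out$n2[k] <- sum(g == prs[2, k])
    if (out$n1[k] < 2 || out$n2[k] < 2) next
    a <- anosim(beta[sel, sel, drop = FALSE], g, n_perm = n_perm,
                seed = derive_seed(seed, k))
    out$r_statistic[k] <- a$r_statistic
    out$p_value[k] <- a$p_value
  }
  out
}
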