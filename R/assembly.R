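# assembly: phylogenetic (betaMNTD/betaNTI) and taxonomic (Raup-Crick
# Bray-Curtis) null models, and the five-way ecological process rule.

PROCESS_LEVELS <- c("heterogeneous_selection", "homogeneous_selection",
                    "dispersal_limitation", "homogenizing_dispersal",
                    "undominated")

# Weight matrix (taxa x samples) for beta-MNTD: relative abundances
# within each sample over the supplied taxa, or 1/richness when
# unweighted.
mntd_weights <- function(counts, weighted) {
  W <- t(counts)
  if (weighted) {
    tot <- colSums(W)
    if (any(tot == 0)) stop("empty sample(s): ",
                            paste(colnames(W)[tot == 0], collapse = ", "),
                            call. = FALSE)
    sweep(W, 2, tot, "/")
  } else {
    P <- (W > 0) * 1
    sweep(P, 2, colSums(P), "/")
  }
}

#' Between-sample mean nearest taxon distance (betaMNTD)
#'
#' For two communities A and B,
#' `0.5 * (sum_i f_iA min_{j in B} d(i, j) + sum_j f_jB min_{i in A} d(j, i))`
#' with `f` the within-sample relative abundances over present taxa
#' (`1/richness` when `weighted = FALSE`) and `d` the patristic
#' distance. Identical communities score 0.
#'
#' @param xa,xb Named abundance vectors over taxa (tree tips).
#' @param tree An [ape::phylo] tree covering the present taxa.
#' @param weighted Abundance-weighted (default) or presence-based.
#' @return The betaMNTD value.
#' @export
beta_mntd <- function(xa, xb, tree, weighted = TRUE) {
  taxa <- union(names(xa)[xa > 0], names(xb)[xb > 0])
  if (!length(names(xa)[xa > 0]) || !length(names(xb)[xb > 0]))
    stop("betaMNTD is undefined for an empty sample", call. = FALSE)
  check_tip_coverage(tree, taxa)
  counts <- rbind(a = xa[taxa], b = xb[taxa])
  counts[is.na(counts)] <- 0
  colnames(counts) <- taxa
  D <- patristic_distances(tree, taxa)
  W <- mntd_weights(counts, weighted)
  .cpp_beta_mntd(D, W)[1, 2]
}

#' Pairwise betaMNTD matrix
#'
#' @param counts Count matrix (samples x ASVs).
#' @param tree Tree covering the table's ASVs.
#' @param weighted Abundance-weighted (default).
#' @return Symmetric matrix of betaMNTD values with sample ids.
#' @export
beta_mntd_matrix <- function(counts, tree, weighted = TRUE) {
  counts <- validate_asv_table(counts)
  check_tip_coverage(tree, colnames(counts))
  D <- patristic_distances(tree, colnames(counts))
  W <- mntd_weights(counts, weighted)
  out <- .cpp_beta_mntd(D, W)
  dimnames(out) <- list(rownames(counts), rownames(counts))
  out
}

#' Beta nearest taxon index (betaNTI)
#'
#' Standardised effect size of betaMNTD against a null that shuffles
#' taxon labels across the tips of the tree (regional-pool shuffle):
#' `(obs - mean(null)) / sd(null)` per sample pair. `betaNTI > 2`
#' indicates heterogeneous selection, `< -2` homogeneous selection;
#' `|betaNTI| < 2` leaves turnover to the stochastic classes.
#'
#' @param counts Count matrix (samples x ASVs); for subcommunity
#'   analyses pass the re-normalised sub-table (the tree is pruned to
#'   its taxa).
#' @param tree Tree covering the table's ASVs.
#' @param n_null Null replicates (default 999).
#' @param seed Optional seed.
#' @param weighted Abundance-weighted betaMNTD (default).
#' @param exhaustive Enumerate all taxon permutations instead of
#'   sampling (tiny trees only; overrides `n_null`).
#' @return Symmetric matrix of betaNTI values; pairs with a degenerate
#'   null (`sd = 0`) are `NA` and counted in attribute `n_degenerate`.
#'   Attributes `bmntd_obs`, `null_mean`, `null_sd` carry the pieces.
#' @export
beta_nti <- function(counts, tree, n_null = 999, seed = NULL,
                     weighted = TRUE, exhaustive = FALSE) {
  counts <- validate_asv_table(counts)
  check_tip_coverage(tree, colnames(counts))
  taxa <- colnames(counts)
  t_n <- length(taxa)
  D <- patristic_distances(tree, taxa)
  W <- mntd_weights(counts, weighted)
  if (exhaustive) {
    perms <- all_permutations(t_n) - 1L
  } else {
    perms <- with_seed(seed, t(replicate(n_null, sample.int(t_n)))) - 1L
  }
  res <- .cpp_beta_nti(D, W, perms)
  z <- (res$obs - res$mean) / res$sd
  degenerate <- res$sd < 1e-12
  z[degenerate] <- NA_real_
  diag(z) <- 0
  ids <- rownames(counts)
  dimnames(z) <- list(ids, ids)
  attr(z, "n_degenerate") <- (sum(degenerate) - nrow(z)) / 2
  attr(z, "bmntd_obs") <- structure(res$obs, dimnames = dimnames(z))
  attr(z, "null_mean") <- res$mean
  attr(z, "null_sd") <- res$sd
  z
}

# One null community: pick `rich` taxa with probability proportional to
# regional occupancy (without replacement), give each one individual,
# then allocate the remaining reads among the picked taxa proportional
# to regional relative abundance.
rc_null_community <- function(n_taxa, rich, depth, occ, relab) {
  picked <- sample.int(n_taxa, rich, prob = occ)
  x <- numeric(n_taxa)
  x[picked] <- 1
  if (depth > rich) {
    extra <- rmultinom(1, depth - rich, prob = relab[picked])[, 1]
    x[picked] <- x[picked] + extra
  }
  x
}

#' Raup-Crick null deviation of Bray-Curtis (RCbray)
#'
#' Per sample pair, compares the observed Bray-Curtis dissimilarity
#' with a null distribution built by probabilistic re-assembly: each
#' sample's observed richness and read total are preserved; taxa enter
#' with probability proportional to regional occupancy and the
#' remaining reads are allocated proportional to regional relative
#' abundance. `RC = 2 * ((n_less + 0.5 n_equal) / n_null) - 1`, in
#' `[-1, 1]`; values above 0.95 flag dispersal limitation, below -0.95
#' homogenizing dispersal.
#'
#' Null communities are drawn once per sample and reused across pairs:
#' each pair's null distribution is unchanged, only independence
#' between pairs is sacrificed, and RC values are consumed marginally.
#'
#' @param counts Count matrix (samples x ASVs).
#' @param n_null Null replicates (default 999).
#' @param seed Optional seed.
#' @param tie_tol Relative tolerance for counting a null draw as tying
#'   the observed value (default 1e-10).
#' @return Symmetric matrix of RCbray values in `[-1, 1]`.
#' @export
raup_crick_bray <- function(counts, n_null = 999, seed = NULL,
                            tie_tol = 1e-10) {
  counts <- validate_asv_table(counts)
  if (nrow(counts) < 2) stop("need >= 2 samples", call. = FALSE)
  occ <- colMeans(counts > 0)
  relab <- colSums(counts) / sum(counts)
  pool <- sum(occ > 0)
  rich <- rowSums(counts > 0)
  depth <- rowSums(counts)
  if (any(rich == 0)) stop("empty sample(s)", call. = FALSE)
  if (any(rich > pool))
    stop("sample richness exceeds regional pool size", call. = FALSE)
  ns <- nrow(counts); nt <- ncol(counts)
  obs <- bray_curtis(counts)
  nulls <- with_seed(seed, lapply(seq_len(ns), function(s) {
    vapply(seq_len(n_null), function(k)
      rc_null_community(nt, rich[s], depth[s], occ, relab),
      numeric(nt))
  }))
  rc <- matrix(0, ns, ns, dimnames = dimnames(obs))
  for (a in seq_len(ns - 1)) {
    NA_ <- nulls[[a]]
    for (b in (a + 1):ns) {
      NB <- nulls[[b]]
      bc <- colSums(abs(NA_ - NB)) / colSums(NA_ + NB)
      o <- obs[a, b]
      tol <- tie_tol * pmax(abs(bc), abs(o), 1e-300)
      eq <- abs(bc - o) <= tol
      less <- bc < o & !eq
      val <- 2 * ((sum(less) + 0.5 * sum(eq)) / n_null) - 1
      rc[a, b] <- rc[b, a] <- val
    }
  }
  rc
}

#' Five-way ecological process classification
#'
#' Pure decision rule on (betaNTI, RCbray) per sample pair:
#' `betaNTI > nti_cut` heterogeneous selection; `betaNTI < -nti_cut`
#' homogeneous selection; otherwise `RC > rc_cut` dispersal limitation,
#' `RC < -rc_cut` homogenizing dispersal, else undominated. Boundary
#' ties fall to the non-selection / non-dominant side (strict
#' inequalities).
#'
#' @param bnti betaNTI matrix (NA pairs are excluded and counted).
#' @param rc RCbray matrix sharing ids.
#' @param nti_cut Selection threshold (default 2).
#' @param rc_cut Dispersal threshold (default 0.95).
#' @return Object of class `assembly_classification`: long data frame
#'   `sample_i`, `sample_j`, `beta_nti`, `rc_bray`, `process`, plus an
#'   `n_excluded` attribute.
#' @export
classify_processes <- function(bnti, rc, nti_cut = 2, rc_cut = 0.95) {
  al <- align_dist(bnti, rc)
  bnti <- al[[1]]; rc <- al[[2]]
  idx <- which(lower.tri(bnti), arr.ind = TRUE)
  b <- bnti[lower.tri(bnti)]
  r <- rc[lower.tri(rc)]
  proc <- ifelse(b > nti_cut, "heterogeneous_selection",
          ifelse(b < -nti_cut, "homogeneous_selection",
          ifelse(r > rc_cut, "dispersal_limitation",
          ifelse(r < -rc_cut, "homogenizing_dispersal", "undominated"))))
  proc[is.na(b)] <- NA
  out <- data.frame(
    sample_i = rownames(bnti)[idx[, 1]],
    sample_j = rownames(bnti)[idx[, 2]],
    beta_nti = b, rc_bray = r,
    process = factor(proc, levels = PROCESS_LEVELS),
    stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- sum(is.na(proc))
  class(out) <- c("assembly_classification", "data.frame")
  out
}

#' Process fractions per stratum
#'
#' Fraction of classified pairs assigned to each of the five processes,
#' with deterministic (two selection classes) and stochastic (the other
#' three) totals. When `strata` is given, only within-stratum pairs are
#' counted and fractions are reported per stratum.
#'
#' @param cls An `assembly_classification`.
#' @param strata Optional named vector mapping sample id to stratum.
#' @return Data frame of fractions per stratum (rows sum to 1 over the
#'   five process columns).
#' @export
process_fractions <- function(cls, strata = NULL) {
  df <- as.data.frame(cls)
  df <- df[!is.na(df$process), , drop = FALSE]
  if (is.null(strata)) {
    df$stratum <- "all"
  } else {
    si <- strata[df$sample_i]; sj <- strata[df$sample_j]
    df <- df[!is.na(si) & si == sj, , drop = FALSE]
    df$stratum <- strata[df$sample_i]
  }
  out <- do.call(rbind, lapply(split(df, df$stratum), function(d) {
    fr <- prop.table(table(d$process))
    data.frame(stratum = d$stratum[1], n_pairs = nrow(d),
               as.list(fr), check.names = FALSE,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out$deterministic <- out$heterogeneous_selection +
    out$homogeneous_selection
  out$stochastic <- 1 - out$deterministic
  out
}
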