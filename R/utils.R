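# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
# The caller's .Random.seed is restored afterwards so library code does
# not perturb user-level random streams. seed = NULL means "use the
# current stream" (no isolation).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministic derived seed for a sub-stage; stays inside 32-bit range.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + offset) %% 2147483587 + 1)
}

# All n! permutations of seq_len(n), one per row. Guarded: enumeration is
# only meant for exhaustive permutation tests on tiny n.
all_permutations <- function(n) {
  stopifnot(n >= 1L, n <= 8L)
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    idx <- row:(row + nrow(sub) - 1L)
    out[idx, 1L] <- k
    out[idx, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
    row <- row + nrow(sub)
  }
  out
}

# Lower-triangle vector of a symmetric matrix, pair order matching
# which(lower.tri(m)).
lower_vec <- function(m) m[lower.tri(m)]

# Validate a square symmetric distance matrix with ids; returns it with
# dimnames enforced.
check_dist_matrix <- function(d, name = deparse(substitute(d))) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d))
    stop(name, " is not square", call. = FALSE)
  if (is.null(rownames(d))) rownames(d) <- colnames(d)
  if (is.null(rownames(d)))
    rownames(d) <- colnames(d) <- paste0("S", seq_len(nrow(d)))
  if (max(abs(d - t(d)), na.rm = TRUE) > 1e-8)
    stop(name, " is not symmetric", call. = FALSE)
  d
}

# Align two (or more) distance matrices on common ids, preserving the
# order of the first.
align_dist <- function(...) {
  mats <- lapply(list(...), check_dist_matrix)
  ids <- rownames(mats[[1L]])
  for (m in mats[-1L]) {
    if (!setequal(ids, rownames(m)))
      stop("distance matrices do not share sample ids", call. = FALSE)
  }
  lapply(mats, function(m) m[ids, ids, drop = FALSE])
}
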