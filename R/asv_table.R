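# core_io: reading, writing and normalising ASV count tables.
#
# The canonical in-memory representation is a plain integer matrix with
# samples as rows and ASVs as columns, carrying ids in dimnames. All
# downstream functions consume this shape.

#' Validate an ASV count table
#'
#' Checks the canonical samples-by-ASVs count matrix: nonnegative integer
#' entries, unique sample and ASV ids. Returns the matrix (storage mode
#' coerced to integer-valued double is accepted).
#'
#' @param counts Numeric matrix, samples in rows, ASVs in columns, with
#'   dimnames.
#' @return The validated matrix.
#' @export
validate_asv_table <- function(counts) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (!is.numeric(counts)) stop("counts must be numeric", call. = FALSE)
  bad <- which(counts < 0 | !is.finite(counts) |
                 abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "invalid count at row '%s', column '%s': %s",
      rownames(counts)[bad[1, 1]] %||% bad[1, 1],
      colnames(counts)[bad[1, 2]] %||% bad[1, 2],
      format(counts[bad[1, , drop = FALSE]])), call. = FALSE)
  }
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("S", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("ASV", seq_len(ncol(counts)))
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample ids in count table", call. = FALSE)
  if (anyDuplicated(colnames(counts)))
    stop("duplicate ASV ids in count table", call. = FALSE)
  counts
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an ASV count table
#'
#' Supports tab-separated tables (ids in the first column) and the dense
#' or sparse BIOM-JSON layout. BIOM stores observations (ASVs) as rows;
#' those tables are transposed on read so the in-memory orientation is
#' always samples-as-rows.
#'
#' @param path Path to the file.
#' @param format `"tsv"` or `"biom-json"`.
#' @param orientation For TSV input: `"auto"` guesses (a table wider than
#'   tall is taken as samples-in-rows), `"samples"` forces rows = samples,
#'   `"asvs"` forces rows = ASVs (transposed on read).
#' @return Integer count matrix, samples x ASVs.
#' @export
read_asv_table <- function(path, format = c("tsv", "biom-json"),
                           orientation = c("auto", "samples", "asvs")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "biom-json") {
    return(read_biom_json(path))
  }
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1L, drop = FALSE], 2,
                                              as.numeric))), arr.ind = TRUE)
    stop(sprintf("non-numeric cell at row '%s', column '%s'",
                 ids[bad[1, 1]], colnames(m)[bad[1, 2]]), call. = FALSE)
  }
  rownames(m) <- ids
  if (orientation == "asvs" ||
      (orientation == "auto" && nrow(m) > ncol(m))) {
    m <- t(m)
  }
  validate_asv_table(m)
}

# Minimal BIOM-JSON (format 1.0) reader: dense and sparse matrix_type.
read_biom_json <- function(path) {
  b <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  obs <- vapply(b$rows, function(r) r$id, character(1))
  smp <- vapply(b$columns, function(c) c$id, character(1))
  m <- matrix(0, nrow = length(obs), ncol = length(smp),
              dimnames = list(obs, smp))
  if (identical(b$matrix_type, "dense")) {
    for (i in seq_along(b$data)) m[i, ] <- unlist(b$data[[i]])
  } else {
    for (trip in b$data) {
      m[trip[[1]] + 1L, trip[[2]] + 1L] <- trip[[3]]
    }
  }
  validate_asv_table(t(m))
}

#' Write an ASV count table as canonical TSV
#'
#' Samples as rows; first column header is `sample_id`. The dialect
#' round-trips through [read_asv_table()] bit-identically.
#'
#' @param counts Count matrix (samples x ASVs).
#' @param path Output path.
#' @export
write_asv_table <- function(counts, path) {
  counts <- validate_asv_table(counts)
  df <- data.frame(sample_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-sample relative abundances
#'
#' @param counts Count matrix (samples x ASVs).
#' @return Matrix of the same shape whose rows sum to 1. Rows with zero
#'   total are left as all-zero with a warning.
#' @export
relative_abundance <- function(counts) {
  counts <- validate_asv_table(counts)
  tot <- rowSums(counts)
  if (any(tot == 0))
    warning("samples with zero total reads: ",
            paste(rownames(counts)[tot == 0], collapse = ", "))
  sweep(counts, 1, pmax(tot, 1), "/")
}

#' Rarefy a count table to even depth
#'
#' Subsamples each sample's reads without replacement down to `depth`.
#' The default depth is the minimum sample total, the usual
#' even-depth normalisation rule for amplicon tables.
#'
#' @param counts Count matrix (samples x ASVs).
#' @param depth Target reads per sample; defaults to `min(rowSums(counts))`.
#' @param seed Optional integer seed; the caller's RNG state is preserved.
#' @param drop_low Drop (with a warning) samples whose total is below
#'   `depth`; if `FALSE` such samples raise an error.
#' @return Rarefied count matrix; every retained row sums to `depth`.
#' @export
rarefy <- function(counts, depth = NULL, seed = NULL, drop_low = TRUE) {
  counts <- validate_asv_table(counts)
  tot <- rowSums(counts)
  if (is.null(depth)) depth <- min(tot)
  if (!is.numeric(depth) || depth <= 0)
    stop("depth must be a positive integer", call. = FALSE)
  depth <- as.integer(round(depth))
  low <- tot < depth
  if (any(low)) {
    if (!drop_low)
      stop("samples below target depth: ",
           paste(rownames(counts)[low], collapse = ", "), call. = FALSE)
    warning("dropping ", sum(low), " sample(s) below depth ", depth, ": ",
            paste(rownames(counts)[low], collapse = ", "))
    counts <- counts[!low, , drop = FALSE]
    tot <- tot[!low]
  }
  with_seed(seed, {
    out <- counts
    for (i in seq_len(nrow(counts))) {
      if (tot[i] == depth) next
      reads <- rep.int(seq_len(ncol(counts)), counts[i, ])
      keep <- sample.int(tot[i], depth)
      out[i, ] <- tabulate(reads[keep], nbins = ncol(counts))
    }
    out
  })
}

#' Good's coverage per sample
#'
#' Coverage is `1 - F1/N` where `F1` is the number of singleton ASVs in
#' the sample and `N` the sample's read total; a completeness-of-sampling
#' diagnostic.
#'
#' @param counts Count matrix (samples x ASVs).
#' @return Named numeric vector in `[0, 1]`; `NA` for empty samples.
#' @export
goods_coverage <- function(counts) {
  counts <- validate_asv_table(counts)
  tot <- rowSums(counts)
  f1 <- rowSums(counts == 1)
  out <- ifelse(tot > 0, 1 - f1 / tot, NA_real_)
  names(out) <- rownames(counts)
  out
}

#' Read sample metadata
#'
#' CSV with required columns `sample_id`, `season`, `landform`,
#' `dist_to_mouth_km` and the nine environmental factor columns given by
#' [env_factors()].
#'
#' @param path CSV path.
#' @param require_env Require all nine factor columns (default `TRUE`).
#' @return Data frame keyed by `sample_id`.
#' @export
read_sample_metadata <- function(path, require_env = TRUE) {
  md <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "season", "landform", "dist_to_mouth_km")
  if (require_env) need <- c(need, env_factors())
  miss <- setdiff(need, names(md))
  if (length(miss))
    stop("metadata missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(md$sample_id))
    stop("duplicate sample ids in metadata", call. = FALSE)
  if (any(md$dist_to_mouth_km < 0))
    stop("dist_to_mouth_km must be nonnegative", call. = FALSE)
  rownames(md) <- md$sample_id
  md
}
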