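# taxa_partition: six-way abundance classification of ASVs.
#
# Categories follow the conditionally-rare framework: with per-sample
# relative abundances of an ASV summarised by (min, max) across samples,
#   AAT  always abundant        min >= abundant_cut
#   CAT  conditionally abundant max >= abundant_cut, rare_cut <= min < abundant_cut
#   CRAT cond. rare & abundant  max >= abundant_cut, min < rare_cut
#   MT   moderate               max <  abundant_cut, min >= rare_cut
#   CRT  conditionally rare     max <  abundant_cut, rare_cut <= max, min < rare_cut
#   ART  always rare            max <  rare_cut
# Boundary convention: ">=" at both cuts (a tie at the rare cut counts
# as not-rare), mirroring the stated inequalities.

ABUNDANCE_CATEGORIES <- c("AAT", "CAT", "CRAT", "MT", "CRT", "ART")

#' Classify ASVs into six abundance categories
#'
#' @param counts Count matrix (samples x ASVs), normally the rarefied
#'   table.
#' @param rare_cut Rare threshold on relative abundance (default 0.01% =
#'   `1e-4`).
#' @param abundant_cut Abundant threshold (default 1% = `1e-2`).
#' @return Object of class `partition_result`: a list with `table` (data
#'   frame asv_id, category, min/max/mean relative abundance), `dropped`
#'   (ids absent from every sample) and the thresholds used.
#' @export
classify_asvs <- function(counts, rare_cut = 1e-4, abundant_cut = 1e-2) {
  stopifnot(rare_cut > 0, abundant_cut > rare_cut, abundant_cut < 1)
  counts <- validate_asv_table(counts)
  if (nrow(counts) < 1) stop("table has no samples", call. = FALSE)
  rel <- relative_abundance(counts)
  tot <- colSums(counts)
  dropped <- colnames(counts)[tot == 0]
  keep <- tot > 0
  rel <- rel[, keep, drop = FALSE]
  mn <- apply(rel, 2, min)
  mx <- apply(rel, 2, max)
  cat <- ifelse(mn >= abundant_cut, "AAT",
         ifelse(mx >= abundant_cut & mn >= rare_cut, "CAT",
         ifelse(mx >= abundant_cut, "CRAT",
         ifelse(mx < rare_cut, "ART",
         ifelse(mn >= rare_cut, "MT", "CRT")))))
  res <- list(
    table = data.frame(
      asv_id = colnames(rel),
      category = factor(cat, levels = ABUNDANCE_CATEGORIES),
      min_relabund = unname(mn),
      max_relabund = unname(mx),
      mean_relabund = unname(colMeans(rel)),
      stringsAsFactors = FALSE),
    dropped = dropped,
    rare_cut = rare_cut,
    abundant_cut = abundant_cut)
  class(res) <- "partition_result"
  res
}

#' @export
print.partition_result <- function(x, ...) {
  cat("Abundance-class partition of", nrow(x$table), "ASVs",
      sprintf("(rare < %g, abundant >= %g)\n", x$rare_cut, x$abundant_cut))
  print(table(x$table$category))
  if (length(x$dropped))
    cat(length(x$dropped), "ASV(s) absent everywhere were dropped\n")
  invisible(x)
}

#' Extract the sub-table of selected abundance categories
#'
#' Typical selections: `"CRAT"` (the abundant fraction) and
#' `c("CRT", "ART")` (the rare fraction).
#'
#' @param counts Count matrix the partition was computed from (or a
#'   compatible one sharing ASV ids).
#' @param part A `partition_result`.
#' @param which Character vector of category names.
#' @return Column-subset count matrix; sample set unchanged.
#' @export
subcommunity <- function(counts, part, which) {
  stopifnot(inherits(part, "partition_result"))
  which <- match.arg(which, ABUNDANCE_CATEGORIES, several.ok = TRUE)
  ids <- part$table$asv_id[part$table$category %in% which]
  ids <- intersect(colnames(counts), ids)
  if (!length(ids)) warning("selection yields an empty table")
  counts[, ids, drop = FALSE]
}

#' Richness and abundance shares per category
#'
#' @param part A `partition_result`.
#' @param taxonomy Optional named character vector mapping asv_id to
#'   phylum; unknown ids are reported as `"Unassigned"`.
#' @return Data frame with per-category (optionally per-phylum) richness
#'   count, richness percentage and mean relative-abundance percentage.
#' @export
partition_summary <- function(part, taxonomy = NULL) {
  stopifnot(inherits(part, "partition_result"))
  tb <- part$table
  grp <- list(category = tb$category)
  if (!is.null(taxonomy)) {
    ph <- taxonomy[tb$asv_id]
    ph[is.na(ph)] <- "Unassigned"
    grp$phylum <- ph
  }
  agg <- aggregate(
    cbind(richness = rep(1L, nrow(tb)), abund = tb$mean_relabund),
    by = grp, FUN = sum, drop = TRUE)
  agg$richness_pct <- 100 * agg$richness / nrow(tb)
  agg$abundance_pct <- 100 * agg$abund / sum(tb$mean_relabund)
  agg$abund <- NULL
  agg[order(agg$category), , drop = FALSE]
}
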