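## ---------------------------------------------------------------------------
## Bivalency: co-occurrence of two marks on the same genes, correlation of
## their per-gene densities, and attribution of that correlation to a subset
## by remove-and-recompute.
## ---------------------------------------------------------------------------

#' Co-occurrence of two marks over a gene universe
#'
#' Counts genes of the universe marked by both modifications and reports the
#' co-marked fraction.  Percentages are conventionally reported rounded to the
#' nearest integer percent.
#'
#' @param marked_a,marked_b character vectors of marked gene ids (each a
#'   subset of `universe`).
#' @param universe character vector of universe gene ids.
#' @param mark_a,mark_b optional mark names for labelling.
#' @return List of class `CoOccurrence`: `n_universe`, `n_both`, `fraction`,
#'   `percent` (integer-rounded), `genes` (the co-marked ids), mark names.
#' @export
co_occurrence <- function(marked_a, marked_b, universe,
                          mark_a = "mark_a", mark_b = "mark_b") {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe")
  if (length(setdiff(marked_a, universe)) ||
      length(setdiff(marked_b, universe))) {
    stop("marked sets must be subsets of the universe")
  }
  both <- sort(intersect(intersect(marked_a, marked_b), universe))
  structure(list(
    mark_a = mark_a, mark_b = mark_b,
    n_universe = length(universe),
    n_both = length(both),
    fraction = length(both) / length(universe),
    percent = round(100 * length(both) / length(universe)),
    genes = both
  ), class = "CoOccurrence")
}

#' @export
print.CoOccurrence <- function(x, ...) {
  cat(sprintf("Co-occurrence of %s and %s: %d%% (%d out of %d)\n",
              x$mark_a, x$mark_b, x$percent, x$n_both, x$n_universe))
  invisible(x)
}

#' Pearson correlation of two marks' per-gene densities
#'
#' Correlates the per-gene window densities of two marks over a gene set and
#' attaches the standard t statistic `t = r * sqrt((n - 2) / (1 - r^2))` with
#' its two-sided p-value on n - 2 degrees of freedom.  Densities (not raw
#' window sums) are used so gene length does not confound the correlation.
#'
#' @param gene_signals multi-mark `GeneSignal` frame.
#' @param mark_a,mark_b the two mark names.
#' @param gene_set character vector of gene ids (at least 3, all with
#'   densities for both marks).
#' @param set_id label for the gene set.
#' @return List of class `CorrelationReport`: `n`, `pearson_r`,
#'   `t_statistic`, `p_value`.
#' @export
density_correlation <- function(gene_signals, mark_a, mark_b, gene_set,
                                set_id = "gene_set") {
  gene_set <- unique(as.character(gene_set))
  if (length(gene_set) < 3L) stop("gene_set must contain at least 3 genes")
  da <- density_vector(gene_signals, mark_a, gene_set)
  db <- density_vector(gene_signals, mark_b, gene_set)
  if (stats::sd(da) == 0 || stats::sd(db) == 0) {
    stop("zero variance in densities for set '", set_id,
         "'; correlation undefined")
  }
  n <- length(gene_set)
  r <- stats::cor(da, db)
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(abs(t_stat), df = n - 2, lower.tail = FALSE)
  structure(list(
    mark_a = mark_a, mark_b = mark_b, set_id = set_id,
    n = n, pearson_r = r, t_statistic = t_stat, p_value = p
  ), class = "CorrelationReport")
}

density_vector <- function(gene_signals, mark, gene_set) {
  gs <- gene_signals[gene_signals$mark_name == mark, , drop = FALSE]
  idx <- match(gene_set, gs$gene_id)
  if (anyNA(idx)) {
    stop("gene(s) missing density for mark '", mark, "': ",
         paste(utils::head(gene_set[is.na(idx)], 3L), collapse = ", "))
  }
  gs$density[idx]
}

#' @export
print.CorrelationReport <- function(x, ...) {
  cat(sprintf(
    "Pearson correlation of %s and %s over %s (n = %d): r = %.3f, t = %.3f, p = %.3g\n",
    x$mark_a, x$mark_b, x$set_id, x$n, x$pearson_r, x$t_statistic, x$p_value))
  invisible(x)
}

#' Attribute cross-mark correlation to a gene subset
#'
#' Computes the density correlation over the full universe and again after
#' removing the candidate subset.  A drop in r (`r_full > r_without`)
#' indicates the subset carries part of the cross-mark correlation.
#'
#' @inheritParams density_correlation
#' @param universe character vector of universe gene ids.
#' @param subset character vector of gene ids to remove (subset of universe;
#'   may be empty, in which case both reports are identical).
#' @return List of class `CorrelationAttribution` with elements `full` and
#'   `without_subset` (both `CorrelationReport`) and `r_drop`.
#' @export
correlation_attribution <- function(gene_signals, mark_a, mark_b, universe,
                                    subset) {
  universe <- unique(as.character(universe))
  subset <- unique(as.character(subset))
  if (length(setdiff(subset, universe))) {
    stop("subset must be contained in the universe")
  }
  remaining <- setdiff(universe, subset)
  if (length(remaining) < 3L) {
    stop("fewer than 3 genes remain after removing the subset")
  }
  full <- density_correlation(gene_signals, mark_a, mark_b, universe,
                              set_id = "universe")
  without <- density_correlation(gene_signals, mark_a, mark_b, remaining,
                                 set_id = "universe_minus_subset")
  structure(list(
    full = full,
    without_subset = without,
    r_drop = full$pearson_r - without$pearson_r
  ), class = "CorrelationAttribution")
}

#' @export
print.CorrelationAttribution <- function(x, ...) {
  cat(sprintf("r = %.3f over the universe, %.3f without the subset (drop %.3f)\n",
              x$full$pearson_r, x$without_subset$pearson_r, x$r_drop))
  invisible(x)
}

#' Sets significantly enriched for both marks
#'
#' Intersects two enrichment result frames (one per mark, over the same sets)
#' and returns the set ids called `enriched` in both — candidate bivalent
#' pathways or domains.
#'
#' @param results_a,results_b `EnrichmentResult` frames, each for one mark,
#'   covering the same sets.
#' @return Character vector of dual-enriched set ids.
#' @export
dual_enriched_sets <- function(results_a, results_b) {
  stopifnot(is.data.frame(results_a), is.data.frame(results_b))
  if (!setequal(results_a$set_id, results_b$set_id)) {
    stop("the two result frames cover different set universes")
  }
  ea <- results_a$set_id[results_a$direction == "enriched"]
  eb <- results_b$set_id[results_b$direction == "enriched"]
  sort(intersect(ea, eb))
}
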