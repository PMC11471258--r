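## Stage 1: marker-positive filtering, per-cluster prevalence, and
## neurotransmitter-class composition of the positive population.

#' Filter a single-cell table to marker-positive cells
#'
#' A cell is marker-positive when its raw marker count is at least the
#' configured threshold `tau` (default 1, i.e. non-zero expression). Row
#' order is preserved.
#'
#' @param sc Region-filtered single-cell table ([read_sc_cells()]).
#' @param config An [analysis_config()].
#' @return The subset of `sc` with `marker_count >= config$tau`.
#' @export
filter_marker_positive <- function(sc, config) {
  keep <- sc$marker_count >= config$tau
  out <- sc[keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    empty_error("no marker-positive cells at threshold tau = ", config$tau)
  }
  rownames(out) <- NULL
  attr(out, "excluded") <- c(below_threshold = sum(!keep))
  out
}

## Equal-tailed Jeffreys interval from Beta(x + 1/2, n - x + 1/2), with the
## conventional boundary modification: the lower limit is 0 when x = 0 and
## the upper limit is 1 when x = n, so the interval always contains the
## point estimate x/n.
jeffreys_interval <- function(x, n, conf_level = 0.95) {
  alpha <- 1 - conf_level
  low <- stats::qbeta(alpha / 2, x + 0.5, n - x + 0.5)
  high <- stats::qbeta(1 - alpha / 2, x + 0.5, n - x + 0.5)
  low[x == 0] <- 0
  high[x == n] <- 1
  cbind(ci_low = low, ci_high = high)
}

#' Per-cluster marker-positive prevalence
#'
#' For each cluster present in the region-filtered single-cell table,
#' counts the cells of that cluster (`n_total`), the marker-positive cells
#' among them (`n_pos`), and their ratio `fraction = n_pos / n_total`, with
#' an equal-tailed Jeffreys binomial interval. Clusters with no cell in the
#' table are absent from the result.
#'
#' @param sc Region-filtered single-cell table.
#' @param positives Output of [filter_marker_positive()]; must be a subset
#'   of `sc`.
#' @param taxonomy Taxonomy data.frame; used to annotate each cluster with
#'   its neurotransmitter class.
#' @param config An [analysis_config()]; supplies the confidence level and
#'   strictness.
#' @return A data.frame with columns `cluster_id`, `nt_class`, `n_total`,
#'   `n_pos`, `fraction`, `ci_low`, `ci_high`, one row per cluster, ordered
#'   by `cluster_id`.
#' @export
cluster_prevalence <- function(sc, positives, taxonomy,
                               config = analysis_config()) {
  stray <- setdiff(positives$cell_id, sc$cell_id)
  if (length(stray)) {
    validation_error("positives contain cell_id(s) absent from the single-cell table: ",
         paste(utils::head(stray, 5L), collapse = ", "))
  }
  clusters <- sort(unique(sc$cluster_id))
  n_total <- as.integer(table(factor(sc$cluster_id, levels = clusters)))
  n_pos <- as.integer(table(factor(positives$cluster_id, levels = clusters)))
  ci <- jeffreys_interval(n_pos, n_total, config$conf_level)
  out <- data.frame(
    cluster_id = clusters,
    nt_class = lookup_nt_class(clusters, taxonomy, config$strict,
                               "prevalence"),
    n_total = n_total,
    n_pos = n_pos,
    fraction = n_pos / n_total,
    ci_low = ci[, "ci_low"],
    ci_high = ci[, "ci_high"],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Neurotransmitter-class composition of the marker-positive population
#'
#' Counts marker-positive cells by the neurotransmitter class of their
#' cluster. The composition is over cells, not clusters, so a large
#' positive cluster weighs more than a small one. All four classes are
#' always reported, zeros included.
#'
#' @param positives Output of [filter_marker_positive()]; must be
#'   non-empty.
#' @param taxonomy Taxonomy data.frame.
#' @param strict Logical; error (strict) or warn (lenient) on clusters
#'   missing from the taxonomy.
#' @return A data.frame with columns `nt_class`, `n_pos`, `pct`
#'   (percentage of the positive population, full precision), one row per
#'   class in canonical order, plus attribute `"N_pos"` (total positives).
#' @export
class_composition <- function(positives, taxonomy, strict = TRUE) {
  if (nrow(positives) == 0L) {
    empty_error("no marker-positive cells: composition undefined")
  }
  cls <- lookup_nt_class(positives$cluster_id, taxonomy, strict,
                         "composition")
  n <- as.integer(table(factor(cls, levels = NT_CLASSES)))
  N <- nrow(positives)
  out <- data.frame(
    nt_class = NT_CLASSES,
    n_pos = n,
    pct = 100 * n / N,
    stringsAsFactors = FALSE
  )
  attr(out, "N_pos") <- N
  out
}
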