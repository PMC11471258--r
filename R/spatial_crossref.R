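## Stage 2: restrict spatial cells to relevant cluster-types and impute
## expected marker-positive counts per anatomical structure and
## neurotransmitter class.

#' Select clusters relevant for the spatial cross-reference
#'
#' A cluster is relevant when it showed at least `min_npos` marker-positive
#' cells in the single-cell data (default 1, i.e. any prior detection).
#'
#' @param prev Prevalence table from [cluster_prevalence()].
#' @param min_npos Minimum `n_pos` for relevance.
#' @return Character vector of relevant cluster ids.
#' @export
select_relevant_clusters <- function(prev, min_npos = 1L) {
  rel <- prev$cluster_id[prev$n_pos >= min_npos]
  if (length(rel) == 0L) {
    empty_error("no relevant clusters (no cluster reaches n_pos >= ", min_npos, ")")
  }
  rel
}

#' Cross-tabulate spatial cells by structure and cluster
#'
#' Counts retained spatial cells per (target structure, relevant cluster)
#' pair. Cells of non-relevant clusters are not tabulated; their count is
#' recorded in the `"excluded"` attribute.
#'
#' Clusters absent from the single-cell prevalence table altogether (as
#' opposed to present with zero positives) are a hard error in strict mode
#' and excluded with a warning in lenient mode; imputing `f = 0` silently
#' is forbidden.
#'
#' @param st Spatial-cell table from [read_spatial_cells()] (already
#'   section- and structure-filtered).
#' @param relevant Character vector of relevant cluster ids.
#' @param known Optional character vector of every cluster id the
#'   prevalence table knows about; triggers the strict/lenient handling
#'   above.
#' @param strict Logical; see above.
#' @return A data.frame with columns `structure`, `cluster_id`, `n`
#'   (positive integer counts only), ordered by structure then cluster,
#'   with attribute `"excluded"` = `c(irrelevant_cluster = <count>)`.
#' @export
tabulate_structure_clusters <- function(st, relevant, known = NULL,
                                        strict = TRUE) {
  if (!is.null(known)) {
    unknown <- setdiff(unique(st$cluster_id), known)
    if (length(unknown)) {
      if (strict) {
        validation_error(
          "spatial cluster(s) absent from the prevalence table: ",
          paste(unknown, collapse = ", "))
      }
      warning("excluding ", sum(st$cluster_id %in% unknown),
              " spatial cell(s) of cluster(s) unseen in the single-cell ",
              "data: ", paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  keep <- st$cluster_id %in% relevant
  n_irrelevant <- sum(!keep)
  st <- st[keep, , drop = FALSE]
  if (nrow(st) == 0L) {
    empty_error("no spatial cells of relevant clusters retained")
  }
  tab <- as.data.frame(table(structure = st$structure,
                             cluster_id = st$cluster_id),
                       stringsAsFactors = FALSE)
  names(tab)[names(tab) == "Freq"] <- "n"
  tab <- tab[tab$n > 0L, , drop = FALSE]
  tab <- tab[order(tab$structure, tab$cluster_id), , drop = FALSE]
  tab$n <- as.integer(tab$n)
  rownames(tab) <- NULL
  attr(tab, "excluded") <- c(irrelevant_cluster = n_irrelevant)
  tab
}

#' Impute expected marker-positive counts per structure
#'
#' For each target structure s the expected number of marker-positive cells
#' is `E[s] = sum_k n[s,k] * f_k`, where `n[s,k]` is the number of spatial
#' cells of cluster k in s and `f_k` is that cluster's marker-positive
#' fraction from the single-cell data. The per-class split sums `n[s,k] *
#' f_k` over the clusters of each neurotransmitter class, and composition
#' percentages are `100 * E[s,c] / E[s]`. Every cluster appearing in
#' `counts` must have a prevalence row; silently assuming `f = 0` is
#' forbidden.
#'
#' @param counts Structure-by-cluster counts from
#'   [tabulate_structure_clusters()].
#' @param prev Prevalence table from [cluster_prevalence()].
#' @param taxonomy Taxonomy data.frame.
#' @param strict Logical; passed to the taxonomy lookup.
#' @return A list of class `imputation_report` with elements
#'   \describe{
#'     \item{structures}{data.frame `structure`, `n_cells`,
#'       `expected_pos`.}
#'     \item{by_class}{data.frame `structure`, `nt_class`, `expected`,
#'       `pct` (NA where `expected_pos` is 0); all four classes per
#'       structure.}
#'     \item{provenance}{list with cluster count and exclusion counters
#'       carried from upstream attributes.}
#'   }
#' @export
impute_expected_counts <- function(counts, prev, taxonomy, strict = TRUE) {
  idx <- match(counts$cluster_id, prev$cluster_id)
  if (anyNA(idx)) {
    missing <- unique(counts$cluster_id[is.na(idx)])
    validation_error("spatial cluster(s) missing from the prevalence table: ",
         paste(missing, collapse = ", "))
  }
  f <- prev$fraction[idx]
  cls <- lookup_nt_class(counts$cluster_id, taxonomy, strict, "imputation")
  contrib <- counts$n * f

  structures <- sort(unique(counts$structure))
  s_fac <- factor(counts$structure, levels = structures)
  struct_df <- data.frame(
    structure = structures,
    n_cells = as.integer(tapply(counts$n, s_fac, sum)),
    expected_pos = as.numeric(tapply(contrib, s_fac, sum)),
    stringsAsFactors = FALSE
  )

  grid <- expand.grid(nt_class = NT_CLASSES, structure = structures,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key_counts <- paste(counts$structure, cls)
  key_grid <- paste(grid$structure, grid$nt_class)
  expected <- vapply(key_grid, function(k) {
    sum(contrib[key_counts == k])
  }, numeric(1), USE.NAMES = FALSE)
  e_s <- struct_df$expected_pos[match(grid$structure, struct_df$structure)]
  by_class <- data.frame(
    structure = grid$structure,
    nt_class = grid$nt_class,
    expected = expected,
    pct = ifelse(e_s > 0, 100 * expected / e_s, NA_real_),
    stringsAsFactors = FALSE
  )
  rownames(struct_df) <- rownames(by_class) <- NULL

  excl <- attr(counts, "excluded")
  report <- list(
    structures = struct_df,
    by_class = by_class,
    provenance = list(
      n_clusters = length(unique(counts$cluster_id)),
      excluded = as.list(if (is.null(excl)) integer(0) else excl)
    )
  )
  class(report) <- "imputation_report"
  report
}

#' @export
print.imputation_report <- function(x, ...) {
  cat("Imputed expected marker-positive counts per structure\n")
  print(x$structures, row.names = FALSE)
  cat("\nPer-class split\n")
  print(x$by_class, row.names = FALSE, digits = 4)
  invisible(x)
}
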