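## End-to-end pipeline, run manifest, and the plain-text composition
## report. The analysis/ scripts and the test-suite drive the pipeline
## through these functions; there is no separate command-line wrapper.

#' Run the full cross-reference pipeline
#'
#' Chains the stages: read/validate inputs, filter marker-positive cells,
#' estimate per-cluster prevalence, summarise class composition, select
#' relevant clusters, tabulate spatial cells and impute expected
#' marker-positive counts per structure. Inputs may be file paths (TSV) or
#' in-memory data.frames with the same schemas.
#'
#' @param sc Single-cell table or path.
#' @param taxonomy Taxonomy table or path.
#' @param spatial Spatial-cell table or path.
#' @param config An [analysis_config()].
#' @param map Optional [structure_map()]; defaults to the prefix map over
#'   `config$structures`.
#' @param out_dir Optional directory; when given, writes `prevalence.tsv`,
#'   `composition.tsv`, `imputation.tsv`, `report.json` and
#'   `manifest.json` there.
#' @return List with `prevalence`, `composition`, `imputation`
#'   (an `imputation_report`) and `manifest`.
#' @export
run_pipeline <- function(sc, taxonomy, spatial, config = analysis_config(),
                         map = structure_map(config$structures),
                         out_dir = NULL) {
  digests <- list()
  if (is.character(taxonomy)) {
    digests$taxonomy <- unname(tools::md5sum(taxonomy))
    taxonomy <- read_taxonomy(taxonomy)
  }
  if (is.character(sc)) {
    digests$sc <- unname(tools::md5sum(sc))
    sc <- read_sc_cells(sc, taxonomy, config)
  } else {
    sc <- sc[config$whole_table_denominator | sc$region == config$region, ,
             drop = FALSE]
    if (nrow(sc) == 0L) {
      empty_error("no cells in region '", config$region, "'")
    }
  }
  if (is.character(spatial)) {
    digests$spatial <- unname(tools::md5sum(spatial))
    spatial <- read_spatial_cells(spatial, map, config)
  } else {
    spatial$structure <- roll_up_structure(spatial$structure, map)
    spatial <- spatial[!is.na(spatial$structure), , drop = FALSE]
    if (length(config$sections)) {
      spatial <- spatial[spatial$section_id %in% config$sections, ,
                         drop = FALSE]
    }
    if (nrow(spatial) == 0L) {
      empty_error("no spatial cells in target structures/sections")
    }
  }

  positives <- filter_marker_positive(sc, config)
  prevalence <- cluster_prevalence(sc, positives, taxonomy, config)
  composition <- class_composition(positives, taxonomy, config$strict)
  relevant <- select_relevant_clusters(prevalence, config$min_npos)
  counts <- tabulate_structure_clusters(spatial, relevant,
                                        known = prevalence$cluster_id,
                                        strict = config$strict)
  imputation <- impute_expected_counts(counts, prevalence, taxonomy,
                                       config$strict)

  manifest <- list(
    config = unclass(config),
    input_digests = digests,
    stage_counts = list(
      sc_cells = nrow(sc),
      marker_positive = nrow(positives),
      clusters = nrow(prevalence),
      relevant_clusters = length(relevant),
      spatial_retained = nrow(spatial),
      spatial_tabulated = sum(counts$n),
      spatial_irrelevant = unname(attr(counts, "excluded")["irrelevant_cluster"])
    ),
    version = as.character(utils::packageVersion("atlasxref")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )

  result <- list(prevalence = prevalence, composition = composition,
                 imputation = imputation, manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir, config)
  result
}

write_pipeline_outputs <- function(result, out_dir, config) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_table(result$prevalence, file.path(out_dir, "prevalence.tsv"))
  comp <- result$composition
  comp$N_pos <- attr(result$composition, "N_pos")
  write_table(comp, file.path(out_dir, "composition.tsv"))
  write_table(result$imputation$by_class, file.path(out_dir, "imputation.tsv"))
  jsonlite::write_json(report_json(result, config),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

## Machine-readable report: one record per structure with per-class
## expected counts and composition percentages.
report_json <- function(result, config) {
  imp <- result$imputation
  structures <- lapply(seq_len(nrow(imp$structures)), function(i) {
    s <- imp$structures$structure[i]
    bc <- imp$by_class[imp$by_class$structure == s, , drop = FALSE]
    by_class <- stats::setNames(
      lapply(seq_len(nrow(bc)), function(j) {
        list(expected = bc$expected[j], pct = bc$pct[j])
      }),
      bc$nt_class
    )
    list(acronym = s,
         n_cells = imp$structures$n_cells[i],
         expected_positive = imp$structures$expected_pos[i],
         by_class = by_class)
  })
  list(
    marker = config$marker,
    tau = config$tau,
    sections = config$sections,
    structures = structures,
    overall = list(
      n_positive = attr(result$composition, "N_pos"),
      by_class = stats::setNames(
        lapply(seq_len(nrow(result$composition)), function(j) {
          list(n = result$composition$n_pos[j],
               pct = result$composition$pct[j])
        }),
        result$composition$nt_class
      )
    ),
    provenance = imp$provenance
  )
}

#' Render the composition report as fixed-width text
#'
#' One row per structure with the expected marker-positive count and
#' per-class composition percentage (a dash where the structure's expected
#' count is zero), followed by the overall positive-population class
#' breakdown (all four classes, zeros included).
#'
#' @param composition Output of [class_composition()].
#' @param imputation An `imputation_report`.
#' @return Character scalar (the formatted report).
#' @export
render_report <- function(composition, imputation) {
  classes <- NT_CLASSES
  fmt_pct <- function(x) ifelse(is.na(x), "-", sprintf("%.1f", x))
  header <- sprintf("%-10s %10s %s", "structure", "expected",
                    paste(sprintf("%14s", classes), collapse = " "))
  rows <- vapply(seq_len(nrow(imputation$structures)), function(i) {
    s <- imputation$structures$structure[i]
    bc <- imputation$by_class[imputation$by_class$structure == s, ]
    pct <- bc$pct[match(classes, bc$nt_class)]
    exp_c <- bc$expected[match(classes, bc$nt_class)]
    cells <- sprintf("%6s (%s%%)", sprintf("%.2f", exp_c), fmt_pct(pct))
    sprintf("%-10s %10.2f %s", s, imputation$structures$expected_pos[i],
            paste(sprintf("%14s", cells), collapse = " "))
  }, character(1))
  overall <- sprintf("  %-14s %6d cells (%.1f%%)",
                     composition$nt_class, composition$n_pos,
                     composition$pct)
  paste(c("Imputed marker-positive counts by structure and class",
          header, rows, "",
          sprintf("Overall marker-positive population (N = %d)",
                  attr(composition, "N_pos")),
          overall),
        collapse = "\n")
}
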