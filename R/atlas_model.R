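#' @keywords internal
"_PACKAGE"

## Shared domain types, table I/O and validation.
##
## All tables are plain data.frames with a fixed snake_case schema
## (tab-separated, UTF-8, header row on disk):
##   taxonomy:      cluster_id, cluster_label, nt_class
##   sc_cells:      cell_id, region, cluster_id, marker_count
##   spatial_cells: cell_id, section_id, cluster_id, structure[, x_um, y_um]
## Readers validate invariants and attach filtering provenance as the
## "excluded" attribute so that retained + excluded == input rows.

NT_CLASSES <- c("glutamatergic", "GABAergic", "dopaminergic", "unassigned")

## Classed conditions so callers can tell schema/consistency problems
## (atlasxref_validation_error) from legitimate-but-empty results
## (atlasxref_empty_error).
validation_error <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("atlasxref_validation_error",
                                "atlasxref_error")))
}

empty_error <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("atlasxref_empty_error", "atlasxref_error")))
}

#' Analysis configuration
#'
#' Bundles the knobs shared by every pipeline stage: which marker gene is
#' thresholded, in which dissection region, at what raw-count threshold a
#' cell counts as marker-positive, and which spatial sections and target
#' anatomical structures are in play.
#'
#' @param marker Gene symbol of the marker whose raw count is thresholded
#'   (default `"Ghsr"`, the ghrelin receptor).
#' @param region Dissection-region label the single-cell table is restricted
#'   to (default `"OLF"`, the olfactory-area microdissection).
#' @param tau Positivity threshold on the raw marker count; a cell is
#'   marker-positive when `marker_count >= tau`. Must be a positive integer;
#'   the default 1 realises "non-zero expression".
#' @param sections Character vector of spatial section ids to keep; empty
#'   means keep all sections.
#' @param structures Ordered character vector of target anatomical-structure
#'   acronyms (default `c("MOB", "AOB", "AON")`). Must be non-empty.
#' @param strict Logical; in strict mode an unknown `cluster_id` in a cell
#'   table is an error, in lenient mode it is mapped to the
#'   `"unassigned"` neurotransmitter class with a warning.
#' @param conf_level Confidence level of the Jeffreys binomial interval
#'   attached to each per-cluster prevalence estimate.
#' @param min_npos Minimum scRNA-seq marker-positive cell count for a
#'   cluster to be considered relevant for the spatial cross-reference.
#' @param whole_table_denominator Logical; if `TRUE`, prevalence
#'   denominators use all cells in the input table rather than only the
#'   region-filtered ones. Off by default.
#' @param seed Integer seed, used only by the synthetic-data generator.
#'
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(marker = "Ghsr",
                            region = "OLF",
                            tau = 1L,
                            sections = character(0),
                            structures = c("MOB", "AOB", "AON"),
                            strict = TRUE,
                            conf_level = 0.95,
                            min_npos = 1L,
                            whole_table_denominator = FALSE,
                            seed = NULL) {
  tau <- as.integer(tau)
  if (is.na(tau) || tau < 1L) {
    validation_error("`tau` must be a positive integer (>= 1)")
  }
  structures <- as.character(structures)
  if (length(structures) == 0L) {
    validation_error("`structures` must be a non-empty character vector")
  }
  if (anyDuplicated(structures)) {
    validation_error("`structures` contains duplicate acronyms")
  }
  if (!is.numeric(conf_level) || conf_level <= 0 || conf_level >= 1) {
    validation_error("`conf_level` must lie strictly between 0 and 1")
  }
  cfg <- list(
    marker = as.character(marker),
    region = as.character(region),
    tau = tau,
    sections = as.character(sections),
    structures = structures,
    strict = isTRUE(strict),
    conf_level = conf_level,
    min_npos = as.integer(min_npos),
    whole_table_denominator = isTRUE(whole_table_denominator),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  class(cfg) <- "analysis_config"
  cfg
}

#' Read an analysis configuration from a YAML file
#'
#' The YAML keys mirror the arguments of [analysis_config()]; absent keys
#' take the defaults.
#'
#' @param path Path to a YAML file.
#' @return An `analysis_config` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) validation_error("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    warning("ignoring unknown config keys: ", paste(extra, collapse = ", "))
    raw <- raw[intersect(names(raw), known)]
  }
  do.call(analysis_config, raw)
}

## --- internal validation helpers -----------------------------------------

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    validation_error(sprintf("%s: missing required column(s): %s",
                 what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

read_tsv_file <- function(path, what) {
  if (!file.exists(path)) validation_error(what, " file not found: ", path)
  utils::read.delim(path, sep = "\t", header = TRUE,
                    colClasses = "character",
                    quote = "", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

## Coerce nt_class labels onto the four canonical categories; anything else
## becomes "unassigned" with a warning naming the offending labels.
normalize_nt_class <- function(nt_class) {
  bad <- setdiff(unique(nt_class), NT_CLASSES)
  if (length(bad)) {
    warning("unrecognised nt_class label(s) mapped to 'unassigned': ",
            paste(bad, collapse = ", "))
    nt_class[nt_class %in% bad] <- "unassigned"
  }
  nt_class
}

## --- taxonomy -------------------------------------------------------------

#' Construct a validated taxonomy table
#'
#' @param cluster_id Character vector of unique cluster identifiers.
#' @param cluster_label Free-text cluster labels (defaults to the ids).
#' @param nt_class Neurotransmitter class per cluster; labels outside
#'   `glutamatergic`, `GABAergic`, `dopaminergic`, `unassigned` are mapped
#'   to `unassigned` with a warning.
#' @return A data.frame with columns `cluster_id`, `cluster_label`,
#'   `nt_class`.
#' @export
taxonomy_table <- function(cluster_id, cluster_label = cluster_id, nt_class) {
  cluster_id <- as.character(cluster_id)
  if (anyDuplicated(cluster_id)) {
    dups <- unique(cluster_id[duplicated(cluster_id)])
    validation_error("duplicate cluster_id in taxonomy: ", paste(dups, collapse = ", "))
  }
  df <- data.frame(
    cluster_id = cluster_id,
    cluster_label = as.character(cluster_label),
    nt_class = normalize_nt_class(as.character(nt_class)),
    stringsAsFactors = FALSE
  )
  df
}

#' Read a taxonomy TSV
#'
#' Expects columns `cluster_id`, `cluster_label`, `nt_class`. Duplicate
#' cluster ids are an error; out-of-vocabulary neurotransmitter classes are
#' mapped to `unassigned` with a warning.
#'
#' @param path Path to a tab-separated taxonomy file.
#' @return Validated taxonomy data.frame.
#' @export
read_taxonomy <- function(path) {
  df <- read_tsv_file(path, "taxonomy")
  require_columns(df, c("cluster_id", "cluster_label", "nt_class"), "taxonomy")
  taxonomy_table(df$cluster_id, df$cluster_label, df$nt_class)
}

## Map cluster ids to nt_class, honouring strict/lenient handling of
## clusters missing from the taxonomy.
lookup_nt_class <- function(cluster_id, taxonomy, strict, what) {
  idx <- match(cluster_id, taxonomy$cluster_id)
  if (anyNA(idx)) {
    unknown <- unique(cluster_id[is.na(idx)])
    if (strict) {
      validation_error(sprintf("%s: cluster_id(s) absent from taxonomy: %s",
                   what, paste(unknown, collapse = ", ")))
    }
    warning(sprintf("%s: %d unknown cluster_id(s) treated as unassigned: %s",
                    what, length(unknown), paste(unknown, collapse = ", ")))
  }
  out <- taxonomy$nt_class[idx]
  out[is.na(idx)] <- "unassigned"
  out
}

## --- single-cell table ----------------------------------------------------

#' Construct a validated single-cell table
#'
#' @param cell_id Unique cell identifiers.
#' @param region Dissection-region label per cell.
#' @param cluster_id Taxonomy cluster id per cell.
#' @param marker_count Non-negative integer raw count of the marker gene.
#' @return A data.frame with columns `cell_id`, `region`, `cluster_id`,
#'   `marker_count`.
#' @export
sc_cell_table <- function(cell_id, region, cluster_id, marker_count) {
  cell_id <- as.character(cell_id)
  if (anyDuplicated(cell_id)) {
    validation_error("duplicate cell_id in single-cell table")
  }
  mc_num <- suppressWarnings(as.numeric(marker_count))
  if (anyNA(mc_num)) {
    validation_error("marker_count contains non-numeric values")
  }
  if (any(mc_num < 0) || any(mc_num != floor(mc_num))) {
    validation_error("marker_count must be non-negative integers")
  }
  data.frame(
    cell_id = cell_id,
    region = as.character(region),
    cluster_id = as.character(cluster_id),
    marker_count = as.integer(mc_num),
    stringsAsFactors = FALSE
  )
}

#' Read a single-cell TSV and restrict it to the configured region
#'
#' Expects columns `cell_id`, `region`, `cluster_id`, `marker_count`.
#' Rows outside `config$region` are dropped (unless
#' `config$whole_table_denominator` is set, in which case all rows are
#' kept); the number dropped is recorded in the `"excluded"` attribute.
#' In strict mode a `cluster_id` absent from the taxonomy is an error.
#'
#' @param path Path to a tab-separated single-cell file.
#' @param taxonomy Taxonomy data.frame from [read_taxonomy()].
#' @param config An [analysis_config()].
#' @return Validated, region-filtered single-cell data.frame with an
#'   `"excluded"` attribute (named integer vector).
#' @export
read_sc_cells <- function(path, taxonomy, config) {
  df <- read_tsv_file(path, "sc_cells")
  require_columns(df, c("cell_id", "region", "cluster_id", "marker_count"),
                  "sc_cells")
  tab <- sc_cell_table(df$cell_id, df$region, df$cluster_id, df$marker_count)
  n_in <- nrow(tab)
  if (!config$whole_table_denominator) {
    tab <- tab[tab$region == config$region, , drop = FALSE]
  }
  if (nrow(tab) == 0L) {
    empty_error("no cells in region '", config$region, "'")
  }
  lookup_nt_class(tab$cluster_id, taxonomy, config$strict, "sc_cells")
  rownames(tab) <- NULL
  attr(tab, "excluded") <- c(out_of_region = n_in - nrow(tab))
  tab
}

## --- structure roll-up ----------------------------------------------------

#' Build a structure roll-up map for a target structure set
#'
#' Anatomical atlases annotate cells at layer/substructure resolution
#' (e.g. `MOB-gl`, the glomerular layer of the main olfactory bulb) while
#' the analysis wants whole-structure acronyms. The default map sends any
#' acronym that has a configured target acronym as a prefix to that target
#' (longest match wins), and each target to itself. Explicit entries
#' override the prefix rule; a real-data adapter should supply the atlas's
#' own parcellation-term table through `extra`.
#'
#' @param targets Ordered character vector of target acronyms.
#' @param extra Optional named character vector of explicit
#'   raw-acronym-to-target entries; values must lie in `targets`.
#' @return A list of class `structure_map` with fields `targets` and
#'   `extra`.
#' @export
structure_map <- function(targets, extra = character(0)) {
  targets <- as.character(targets)
  if (length(targets) == 0L) validation_error("targets must be non-empty")
  if (length(extra)) {
    if (is.null(names(extra)) || any(names(extra) == "")) {
      validation_error("`extra` must be a named character vector")
    }
    bad <- setdiff(extra, targets)
    if (length(bad)) {
      validation_error("`extra` maps to acronyms outside the target set: ",
           paste(unique(bad), collapse = ", "))
    }
  }
  structure(list(targets = targets, extra = extra), class = "structure_map")
}

#' Roll raw structure acronyms up to target acronyms
#'
#' Applies a [structure_map()]: explicit entries first, then the
#' longest-prefix rule against the target set. Unmapped acronyms come back
#' as `NA` (to be excluded and counted by the caller). The roll-up is
#' idempotent: target acronyms map to themselves.
#'
#' @param raw Character vector of raw structure acronyms.
#' @param map A `structure_map`.
#' @return Character vector of target acronyms, `NA` where unmapped.
#' @export
roll_up_structure <- function(raw, map) {
  stopifnot(inherits(map, "structure_map"))
  raw <- as.character(raw)
  out <- rep(NA_character_, length(raw))
  if (length(map$extra)) {
    hit <- match(raw, names(map$extra))
    out[!is.na(hit)] <- unname(map$extra[hit[!is.na(hit)]])
  }
  todo <- is.na(out)
  if (any(todo)) {
    # longest-prefix match against the target set
    ord <- order(nchar(map$targets), decreasing = TRUE)
    for (t in map$targets[ord]) {
      cand <- todo & is.na(out) & startsWith(raw, t)
      out[cand] <- t
    }
  }
  out
}

## --- spatial table ----------------------------------------------------------

#' Construct a validated spatial-cell table
#'
#' @param cell_id Unique cell identifiers.
#' @param section_id Section (slide) id per cell.
#' @param cluster_id Taxonomy cluster id per cell.
#' @param structure Anatomical structure acronym per cell.
#' @param x_um,y_um Optional coordinates in micrometres; carried through
#'   but never used in computation.
#' @return A data.frame with columns `cell_id`, `section_id`, `cluster_id`,
#'   `structure` and, when given, `x_um`, `y_um`.
#' @export
spatial_cell_table <- function(cell_id, section_id, cluster_id, structure,
                               x_um = NULL, y_um = NULL) {
  cell_id <- as.character(cell_id)
  if (anyDuplicated(cell_id)) {
    validation_error("duplicate cell_id in spatial table")
  }
  df <- data.frame(
    cell_id = cell_id,
    section_id = as.character(section_id),
    cluster_id = as.character(cluster_id),
    structure = as.character(structure),
    stringsAsFactors = FALSE
  )
  if (!is.null(x_um)) df$x_um <- as.numeric(x_um)
  if (!is.null(y_um)) df$y_um <- as.numeric(y_um)
  df
}

#' Read a spatial-cell TSV, roll structures up, and filter sections
#'
#' Expects columns `cell_id`, `section_id`, `cluster_id`, `structure`
#' (optionally `x_um`, `y_um`). Structures are rolled up via
#' [roll_up_structure()]; rows whose rolled-up structure is not in the
#' target set are excluded, as are rows outside `config$sections` when that
#' is non-empty. Exclusion counts land in the `"excluded"` attribute.
#'
#' @param path Path to a tab-separated spatial-cell file.
#' @param map A [structure_map()] onto the configured target set.
#' @param config An [analysis_config()].
#' @return Validated spatial data.frame with an `"excluded"` attribute
#'   (named integer vector: `off_section`, `unmapped_structure`).
#' @export
read_spatial_cells <- function(path, map, config) {
  df <- read_tsv_file(path, "spatial_cells")
  require_columns(df, c("cell_id", "section_id", "cluster_id", "structure"),
                  "spatial_cells")
  tab <- spatial_cell_table(df$cell_id, df$section_id, df$cluster_id,
                            df$structure,
                            x_um = if ("x_um" %in% names(df)) df$x_um,
                            y_um = if ("y_um" %in% names(df)) df$y_um)
  n_in <- nrow(tab)
  off_section <- 0L
  if (length(config$sections)) {
    keep <- tab$section_id %in% config$sections
    off_section <- sum(!keep)
    tab <- tab[keep, , drop = FALSE]
  }
  rolled <- roll_up_structure(tab$structure, map)
  unmapped <- sum(is.na(rolled))
  tab$structure <- rolled
  tab <- tab[!is.na(tab$structure), , drop = FALSE]
  if (nrow(tab) == 0L) {
    empty_error("no spatial cells in target structures/sections")
  }
  rownames(tab) <- NULL
  attr(tab, "excluded") <- c(off_section = off_section,
                             unmapped_structure = as.integer(unmapped))
  tab
}

## --- generic TSV writer ---------------------------------------------------

#' Write a table as TSV with a stable column order
#'
#' Writes tab-separated UTF-8 with a header row. Numeric fraction columns
#' are serialized with 15 significant digits so that writer-then-reader is
#' the identity on valid tables.
#'
#' @param table A data.frame.
#' @param path Output path; the parent directory must exist.
#' @return Invisibly, the path.
#' @export
write_table <- function(table, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    validation_error("output directory does not exist: ", dir)
  }
  out <- table
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(x) formatC(x, digits = 15, format = "g"))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}
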