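## Small deterministic worked-example tables. Three clusters (one per
## assigned neurotransmitter class), eleven single-cell cells and
## twenty-nine spatial cells; every stage output is checkable by hand:
## fractions (0.5, 0.2, 0), composition (66.7, 33.3, 0, 0)%, expected
## positives MOB 7.0 (glut 5.0, GABA 2.0) and AOB 2.0 (all glut).

#' Worked-example taxonomy (three clusters)
#' @return Taxonomy data.frame: K1 glutamatergic, K2 GABAergic,
#'   K3 dopaminergic.
#' @export
toy_taxonomy <- function() {
  taxonomy_table(
    cluster_id = c("K1", "K2", "K3"),
    cluster_label = c("glut cluster", "GABA cluster", "dopa cluster"),
    nt_class = c("glutamatergic", "GABAergic", "dopaminergic")
  )
}

#' Worked-example single-cell table (11 OLF cells)
#' @return Single-cell data.frame: K1 marker counts (3, 1, 0, 0),
#'   K2 (0, 0, 1, 0, 0), K3 (0, 0).
#' @export
toy_sc_cells <- function() {
  sc_cell_table(
    cell_id = sprintf("C%02d", 1:11),
    region = "OLF",
    cluster_id = rep(c("K1", "K2", "K3"), c(4L, 5L, 2L)),
    marker_count = c(3L, 1L, 0L, 0L, 0L, 0L, 1L, 0L, 0L, 0L, 0L)
  )
}

#' Worked-example spatial table (29 cells on section 60)
#' @return Spatial data.frame: MOB holds 10 K1 + 10 K2 + 5 K3 cells,
#'   AOB holds 4 K1 cells.
#' @export
toy_spatial_cells <- function() {
  spatial_cell_table(
    cell_id = sprintf("S%02d", 1:29),
    section_id = "60",
    cluster_id = c(rep("K1", 10), rep("K2", 10), rep("K3", 5), rep("K1", 4)),
    structure = rep(c("MOB", "AOB"), c(25L, 4L))
  )
}
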