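## Seeded generator of paired single-cell / spatial tables with the
## statistical structure the analysis assumes, plus closed-form ground
## truth for recovery tests.
##
## Count model: a cell of cluster k is marker-positive with probability
## p_k; positive cells get marker_count = 1 + Poisson(lambda), negative
## cells get 0. The analysis consumes only zero vs non-zero at tau = 1, but
## the extra Poisson mass keeps experiments with tau > 1 meaningful.

#' Specify a synthetic paired atlas
#'
#' @param clusters data.frame with columns `cluster_id`, `nt_class`, `p`
#'   (true marker-positivity probability in \[0,1\]) and `n_sc`
#'   (single-cell cells to simulate per cluster, >= 0).
#' @param structures data.frame with columns `acronym` and `n_cells`
#'   (spatial cells to simulate per structure, >= 0).
#' @param theta Numeric matrix of structure-conditional cluster mixing
#'   weights, one row per structure and one column per cluster (dimnames
#'   checked when present); each row must sum to 1 within 1e-9.
#' @param sections data.frame with columns `section_id` and `weight`
#'   (spatial cells are assigned to sections with these probabilities).
#' @param lambda Extra-count Poisson intensity for positive cells
#'   (default 1).
#' @param region Dissection-region label written on every simulated
#'   single-cell row.
#' @param seed Integer seed; mandatory. Two independent substreams are
#'   derived from it so that resizing one table does not perturb the other.
#' @return A list of class `sim_spec`.
#' @export
sim_spec <- function(clusters, structures, theta, sections, lambda = 1,
                     region = "OLF", seed) {
  if (missing(seed) || is.null(seed)) validation_error("`seed` is mandatory")
  require_columns(clusters, c("cluster_id", "nt_class", "p", "n_sc"),
                  "sim_spec$clusters")
  require_columns(structures, c("acronym", "n_cells"), "sim_spec$structures")
  require_columns(sections, c("section_id", "weight"), "sim_spec$sections")
  if (anyDuplicated(clusters$cluster_id)) {
    validation_error("duplicate cluster_id in sim spec")
  }
  if (any(clusters$p < 0 | clusters$p > 1)) {
    validation_error("positivity probabilities p must lie in [0, 1]")
  }
  if (any(clusters$n_sc < 0) || any(clusters$n_sc != floor(clusters$n_sc))) {
    validation_error("n_sc must be non-negative integers")
  }
  if (any(structures$n_cells < 0) ||
      any(structures$n_cells != floor(structures$n_cells))) {
    validation_error("n_cells must be non-negative integers")
  }
  theta <- as.matrix(theta)
  if (nrow(theta) != nrow(structures) || ncol(theta) != nrow(clusters)) {
    validation_error("theta must be ", nrow(structures), " x ", nrow(clusters),
         " (structures x clusters)")
  }
  if (any(theta < 0)) validation_error("theta weights must be non-negative")
  if (any(abs(rowSums(theta) - 1) > 1e-9)) {
    validation_error("each row of theta must sum to 1 (within 1e-9)")
  }
  dimnames(theta) <- list(structures$acronym, clusters$cluster_id)
  if (lambda < 0) validation_error("lambda must be >= 0")
  if (any(sections$weight < 0) || sum(sections$weight) <= 0) {
    validation_error("section weights must be non-negative and sum to > 0")
  }
  spec <- list(
    clusters = clusters,
    structures = structures,
    theta = theta,
    sections = sections,
    lambda = lambda,
    region = as.character(region),
    seed = as.integer(seed)
  )
  class(spec) <- "sim_spec"
  spec
}

#' Default synthetic-atlas specification
#'
#' A compact three-cluster / three-structure spec used by the unit tests
#' and documentation: a glutamatergic, a GABAergic and a dopaminergic
#' cluster with positivity probabilities 0.5, 0.2 and 0, distributed over
#' MOB, AOB and AON with AOB a pure-glutamatergic structure. Cell numbers
#' default to the small worked example (closed-form expected positive
#' counts 7.0 in MOB and 2.0 in AOB) and can be scaled up for sampling
#' experiments.
#'
#' @param n_sc Integer vector of single-cell cells per cluster.
#' @param n_spatial Integer vector of spatial cells per structure
#'   (MOB, AOB, AON).
#' @param seed Integer seed.
#' @return A [sim_spec()].
#' @export
default_sim_spec <- function(n_sc = c(4L, 5L, 2L),
                             n_spatial = c(25L, 4L, 10L),
                             seed = 1L) {
  clusters <- data.frame(
    cluster_id = c("K1", "K2", "K3"),
    nt_class = c("glutamatergic", "GABAergic", "dopaminergic"),
    p = c(0.5, 0.2, 0),
    n_sc = as.integer(n_sc),
    stringsAsFactors = FALSE
  )
  structures <- data.frame(
    acronym = c("MOB", "AOB", "AON"),
    n_cells = as.integer(n_spatial),
    stringsAsFactors = FALSE
  )
  theta <- rbind(
    MOB = c(0.4, 0.4, 0.2),
    AOB = c(1, 0, 0),
    AON = c(0.6, 0.4, 0)
  )
  sections <- data.frame(
    section_id = c("60", "62", "64", "66", "67"),
    weight = rep(0.2, 5),
    stringsAsFactors = FALSE
  )
  sim_spec(clusters, structures, theta, sections,
           lambda = 1, region = "OLF", seed = seed)
}

## Derive the two independent substream seeds from the spec seed.
substream_seeds <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, 2L)
}

#' Simulate the single-cell table of a synthetic atlas
#'
#' For each cluster k, draws `n_sc_k` cells, each marker-positive with
#' probability `p_k`; positive cells receive `marker_count = 1 +
#' rpois(lambda)`, negative cells 0. Fully reproducible given the spec
#' seed.
#'
#' @param spec A [sim_spec()].
#' @return List with elements `cells` (a single-cell data.frame accepted by
#'   the strict-mode readers) and `truth` (per-cluster `p` and realized
#'   positive counts).
#' @export
generate_sc <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  seeds <- substream_seeds(spec$seed)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seeds[1L])
  k <- rep(spec$clusters$cluster_id, spec$clusters$n_sc)
  p <- rep(spec$clusters$p, spec$clusters$n_sc)
  n <- length(k)
  pos <- stats::rbinom(n, 1L, p) == 1L
  count <- integer(n)
  count[pos] <- 1L + stats::rpois(sum(pos), spec$lambda)
  cells <- sc_cell_table(
    cell_id = sprintf("SC%06d", seq_len(n)),
    region = rep(spec$region, n),
    cluster_id = k,
    marker_count = count
  )
  realized <- tapply(pos, factor(k, levels = spec$clusters$cluster_id), sum)
  list(
    cells = cells,
    truth = list(
      p = stats::setNames(spec$clusters$p, spec$clusters$cluster_id),
      realized_n_pos = stats::setNames(as.integer(realized),
                                       spec$clusters$cluster_id)
    )
  )
}

#' Simulate the spatial table of a synthetic atlas
#'
#' For each structure s, draws `n_cells_s` cells with cluster sampled from
#' the mixing weights `theta[s, ]` and section sampled from the section
#' weights. Uses an RNG substream independent of [generate_sc()].
#'
#' @param spec A [sim_spec()].
#' @return List with elements `cells` (a spatial data.frame accepted by the
#'   strict-mode readers) and `truth` (realized structure-by-cluster
#'   counts).
#' @export
generate_spatial <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  seeds <- substream_seeds(spec$seed)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seeds[2L])
  cluster_ids <- spec$clusters$cluster_id
  keep <- spec$structures$n_cells > 0L
  acronyms <- spec$structures$acronym[keep]
  sizes <- spec$structures$n_cells[keep]
  s <- rep(acronyms, sizes)
  k <- character(length(s))
  offset <- 0L
  for (i in seq_along(acronyms)) {
    idx <- offset + seq_len(sizes[i])
    k[idx] <- sample(cluster_ids, sizes[i], replace = TRUE,
                     prob = spec$theta[acronyms[i], ])
    offset <- offset + sizes[i]
  }
  w <- spec$sections$weight / sum(spec$sections$weight)
  sec <- sample(spec$sections$section_id, length(s), replace = TRUE, prob = w)
  cells <- spatial_cell_table(
    cell_id = sprintf("ST%06d", seq_along(s)),
    section_id = sec,
    cluster_id = k,
    structure = s
  )
  realized <- table(structure = s, cluster_id = factor(k, levels = cluster_ids))
  list(cells = cells, truth = list(realized_counts = realized))
}

#' Closed-form ground truth of a synthetic atlas
#'
#' No sampling: the true expected marker-positive count of structure s is
#' `N_s * sum_k theta[s,k] * p_k`, split by neurotransmitter class over the
#' clusters of each class.
#'
#' @param spec A [sim_spec()].
#' @return List with elements `p` (named per-cluster probabilities),
#'   `structures` (data.frame `structure`, `n_cells`,
#'   `true_expected_pos`) and `by_class` (data.frame `structure`,
#'   `nt_class`, `true_expected`).
#' @export
ground_truth <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  p <- spec$clusters$p
  cls <- spec$clusters$nt_class
  N <- spec$structures$n_cells
  exp_sk <- spec$theta * rep(p, each = nrow(spec$theta)) * N
  structures <- data.frame(
    structure = spec$structures$acronym,
    n_cells = N,
    true_expected_pos = rowSums(exp_sk),
    stringsAsFactors = FALSE
  )
  grid <- expand.grid(nt_class = NT_CLASSES,
                      structure = spec$structures$acronym,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$true_expected <- mapply(function(s, c) {
    sum(exp_sk[s, cls == c])
  }, grid$structure, grid$nt_class)
  list(
    p = stats::setNames(p, spec$clusters$cluster_id),
    structures = structures,
    by_class = grid[, c("structure", "nt_class", "true_expected")]
  )
}

#' Simulate a complete paired atlas and optionally write it to disk
#'
#' Convenience wrapper generating the taxonomy, single-cell and spatial
#' tables plus ground truth from one spec. When `out_dir` is given, writes
#' `taxonomy.tsv`, `sc_cells.tsv`, `spatial_cells.tsv` and
#' `ground_truth.json` there.
#'
#' @param spec A [sim_spec()].
#' @param out_dir Optional output directory (created if absent).
#' @return List with `taxonomy`, `sc`, `spatial` (data.frames) and `truth`.
#' @export
simulate_atlas <- function(spec, out_dir = NULL) {
  taxonomy <- taxonomy_table(spec$clusters$cluster_id,
                             nt_class = spec$clusters$nt_class)
  sc <- generate_sc(spec)
  st <- generate_spatial(spec)
  truth <- ground_truth(spec)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table(taxonomy, file.path(out_dir, "taxonomy.tsv"))
    write_table(sc$cells, file.path(out_dir, "sc_cells.tsv"))
    write_table(st$cells, file.path(out_dir, "spatial_cells.tsv"))
    jsonlite::write_json(
      list(p = as.list(truth$p),
           structures = truth$structures,
           by_class = truth$by_class),
      file.path(out_dir, "ground_truth.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  list(taxonomy = taxonomy, sc = sc$cells, spatial = st$cells, truth = truth)
}
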