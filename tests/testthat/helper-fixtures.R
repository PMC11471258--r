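# Shared fixture builders: toy tables on disk, and random simulation specs
# for the oracle-equivalence sweeps.

write_toy_files <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  write_table(toy_taxonomy(), file.path(dir, "taxonomy.tsv"))
  write_table(toy_sc_cells(), file.path(dir, "sc_cells.tsv"))
  write_table(toy_spatial_cells(), file.path(dir, "spatial_cells.tsv"))
  list(dir = dir,
       taxonomy = file.path(dir, "taxonomy.tsv"),
       sc = file.path(dir, "sc_cells.tsv"),
       spatial = file.path(dir, "spatial_cells.tsv"))
}

# Random but valid spec: 2-6 clusters, 1-4 structures, cluster sizes and
# positivity probabilities drawn wide enough to hit boundary cases
# (p = 0 clusters, small clusters) while keeping tables desk-sized.
random_spec <- function(seed) {
  set.seed(seed)
  K <- sample(2:6, 1)
  S <- sample(1:4, 1)
  p <- runif(K)
  p[1] <- runif(1, 0.2, 0.9)                   # guarantee a detectable cluster
  p[sample(2:K, 1)] <- sample(c(0, 1, runif(1)), 1)  # force a boundary sometimes
  clusters <- data.frame(
    cluster_id = sprintf("K%02d", seq_len(K)),
    nt_class = sample(atlasxref:::NT_CLASSES, K, replace = TRUE),
    p = p,
    n_sc = sample(50:150, K, replace = TRUE),
    stringsAsFactors = FALSE
  )
  theta <- matrix(rgamma(S * K, 1), nrow = S)
  theta <- theta / rowSums(theta)
  structures <- data.frame(
    acronym = sprintf("S%02d", seq_len(S)),
    n_cells = sample(100:2000, S, replace = TRUE),
    stringsAsFactors = FALSE
  )
  sections <- data.frame(section_id = c("60", "62"), weight = c(0.5, 0.5),
                         stringsAsFactors = FALSE)
  sim_spec(clusters, structures, theta, sections,
           lambda = runif(1, 0, 2), seed = seed)
}
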