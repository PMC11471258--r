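toy_prevalence <- function() {
  cfg <- analysis_config()
  sc <- toy_sc_cells()
  cluster_prevalence(sc, filter_marker_positive(sc, cfg), toy_taxonomy(), cfg)
}

test_that("relevant clusters are exactly those with a positive cell", {
  prev <- toy_prevalence()
  expect_equal(select_relevant_clusters(prev), c("K1", "K2"))

  none <- prev
  none$n_pos <- 0L
  expect_error(select_relevant_clusters(none), "no relevant",
               class = "atlasxref_empty_error")

  all_pos <- prev
  all_pos$n_pos <- 1L
  expect_equal(select_relevant_clusters(all_pos), prev$cluster_id)

  # configurable minimum
  expect_equal(select_relevant_clusters(prev, min_npos = 2L), "K1")
})

test_that("structure-by-cluster tabulation matches the hand tally", {
  st <- toy_spatial_cells()
  counts <- tabulate_structure_clusters(st, c("K1", "K2"))
  expect_equal(counts$structure, c("AOB", "MOB", "MOB"))
  expect_equal(counts$cluster_id, c("K1", "K1", "K2"))
  expect_equal(counts$n, c(4L, 10L, 10L))
  expect_equal(unname(attr(counts, "excluded")["irrelevant_cluster"]), 5L)
  expect_equal(sum(counts$n) + sum(attr(counts, "excluded")), nrow(st))

  # no-op filter: margins equal raw structure totals
  all_counts <- tabulate_structure_clusters(st, c("K1", "K2", "K3"))
  margins <- tapply(all_counts$n, all_counts$structure, sum)
  expect_equal(as.vector(margins[c("MOB", "AOB")]), c(25L, 4L))

  # structure holding only irrelevant clusters disappears from the table
  only_k3 <- tabulate_structure_clusters(st, "K2")
  expect_false("AOB" %in% only_k3$structure)
})

test_that("unknown spatial clusters are an error in strict mode, a warning in lenient", {
  st <- toy_spatial_cells()
  st$cluster_id[1] <- "K9"
  known <- c("K1", "K2", "K3")
  expect_error(
    tabulate_structure_clusters(st, c("K1", "K2"), known = known,
                                strict = TRUE),
    "K9", class = "atlasxref_validation_error")
  expect_warning(
    counts <- tabulate_structure_clusters(st, c("K1", "K2"), known = known,
                                          strict = FALSE),
    "K9")
  expect_equal(sum(counts$n), 23L)  # one K1 cell lost to the corruption
})

test_that("imputation reproduces the worked example and enforces consistency", {
  prev <- toy_prevalence()
  counts <- tabulate_structure_clusters(toy_spatial_cells(), c("K1", "K2"))
  rep <- impute_expected_counts(counts, prev, toy_taxonomy())

  s <- rep$structures
  expect_equal(s$expected_pos[s$structure == "MOB"], 7)
  expect_equal(s$expected_pos[s$structure == "AOB"], 2)
  bc <- rep$by_class
  expect_equal(bc$expected[bc$structure == "MOB" & bc$nt_class == "glutamatergic"], 5)
  expect_equal(bc$expected[bc$structure == "MOB" & bc$nt_class == "GABAergic"], 2)
  expect_equal(bc$pct[bc$structure == "AOB" & bc$nt_class == "glutamatergic"], 100)

  # every structure's class percentages sum to 100
  for (st_id in s$structure) {
    expect_equal(sum(bc$pct[bc$structure == st_id], na.rm = TRUE), 100,
                 tolerance = 1e-12)
  }

  # cluster present in counts but absent from prevalence is a hard error
  bad <- counts
  bad$cluster_id[1] <- "K7"
  expect_error(impute_expected_counts(bad, prev, toy_taxonomy()),
               "K7", class = "atlasxref_validation_error")
})

test_that("imputation honours the algebraic identities", {
  prev <- toy_prevalence()
  counts <- tabulate_structure_clusters(toy_spatial_cells(), c("K1", "K2"))

  # all f = 1 makes the expectation hit the cell-count ceiling
  prev1 <- prev
  prev1$fraction <- 1
  rep1 <- impute_expected_counts(counts, prev1, toy_taxonomy())
  expect_equal(rep1$structures$expected_pos, as.numeric(rep1$structures$n_cells))

  # single cluster, f = 0.25, n = 8 gives E = 2
  prev_q <- data.frame(cluster_id = "K1", nt_class = "glutamatergic",
                       n_total = 20L, n_pos = 5L, fraction = 0.25,
                       ci_low = 0.1, ci_high = 0.5)
  counts_q <- data.frame(structure = "MOB", cluster_id = "K1", n = 8L)
  rep_q <- impute_expected_counts(counts_q, prev_q, toy_taxonomy())
  expect_equal(rep_q$structures$expected_pos, 2)

  # linearity: duplicating every spatial row of one cluster doubles its
  # contribution and nothing else
  st <- toy_spatial_cells()
  dup <- st[st$cluster_id == "K2", ]
  dup$cell_id <- paste0(dup$cell_id, "_dup")
  st2 <- rbind(st, dup)
  rep_a <- impute_expected_counts(
    tabulate_structure_clusters(st, c("K1", "K2")), prev, toy_taxonomy())
  rep_b <- impute_expected_counts(
    tabulate_structure_clusters(st2, c("K1", "K2")), prev, toy_taxonomy())
  ga <- rep_a$by_class
  gb <- rep_b$by_class
  expect_equal(gb$expected[gb$nt_class == "GABAergic" & gb$structure == "MOB"],
               2 * ga$expected[ga$nt_class == "GABAergic" & ga$structure == "MOB"])
  expect_equal(gb$expected[gb$nt_class == "glutamatergic" & gb$structure == "MOB"],
               ga$expected[ga$nt_class == "glutamatergic" & ga$structure == "MOB"])
})

test_that("imputation agrees with the per-cell oracle and respects bounds", {
  cfg <- analysis_config()
  for (seed in 1:5) {
    sim <- simulate_atlas(random_spec(seed))
    pos <- filter_marker_positive(sim$sc, cfg)
    prev <- cluster_prevalence(sim$sc, pos, sim$taxonomy, cfg)
    relevant <- select_relevant_clusters(prev)
    counts <- tabulate_structure_clusters(sim$spatial, relevant)
    rep <- impute_expected_counts(counts, prev, sim$taxonomy)

    ref <- oracle_expected(sim$spatial, prev)
    expect_equal(rep$structures$structure, ref$structure)
    expect_equal(rep$structures$n_cells, ref$n_cells)
    expect_equal(rep$structures$expected_pos, ref$expected_pos,
                 tolerance = 1e-9)

    # bounds and additivity
    expect_true(all(rep$structures$expected_pos >= 0))
    expect_true(all(rep$structures$expected_pos <= rep$structures$n_cells))
    class_sums <- tapply(rep$by_class$expected, rep$by_class$structure, sum)
    expect_equal(as.vector(class_sums[rep$structures$structure]),
                 rep$structures$expected_pos, tolerance = 1e-9)
  }
})
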