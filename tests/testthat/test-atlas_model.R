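test_that("taxonomy reader validates schema, uniqueness and class vocabulary", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "tax.tsv")

  writeLines(c("cluster_id\tcluster_label\tnt_class",
               "K1\tglut\tglutamatergic",
               "K2\tgaba\tGABAergic",
               "K3\tdopa\tdopaminergic"), path)
  tax <- read_taxonomy(path)
  expect_equal(nrow(tax), 3L)
  expect_equal(tax$nt_class, c("glutamatergic", "GABAergic", "dopaminergic"))

  writeLines(c("cluster_id\tcluster_label\tnt_class",
               "K1\tx\tGlut-unknown"), path)
  expect_warning(tax <- read_taxonomy(path), "unassigned")
  expect_equal(tax$nt_class, "unassigned")

  writeLines(c("cluster_id\tcluster_label\tnt_class",
               "K1\tx\tGABAergic",
               "K1\ty\tGABAergic"), path)
  expect_error(read_taxonomy(path), "duplicate cluster_id",
               class = "atlasxref_validation_error")

  writeLines(c("cluster_id\tcluster_label", "K1\tx"), path)
  expect_error(read_taxonomy(path), "nt_class")
})

test_that("single-cell reader filters to the region and enforces count validity", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "sc.tsv")
  tax <- toy_taxonomy()
  cfg <- analysis_config(region = "OLF", strict = FALSE)

  writeLines(c("cell_id\tregion\tcluster_id\tmarker_count",
               "c1\tOLF\tK1\t3", "c2\tOLF\tK1\t0", "c3\tCTX\tK2\t1",
               "c4\tOLF\tK2\t0", "c5\tCTX\tK3\t0", "c6\tOLF\tK3\t2"), path)
  sc <- read_sc_cells(path, tax, cfg)
  expect_equal(nrow(sc), 4L)
  expect_true(all(sc$region == "OLF"))
  # retained + excluded = input rows
  expect_equal(nrow(sc) + sum(attr(sc, "excluded")), 6L)

  writeLines(c("cell_id\tregion\tcluster_id\tmarker_count",
               "c1\tOLF\tK1\t-1"), path)
  expect_error(read_sc_cells(path, tax, cfg), "non-negative",
               class = "atlasxref_validation_error")

  writeLines(c("cell_id\tregion\tcluster_id\tmarker_count",
               "c1\tOLF\tK9\t1"), path)
  expect_warning(sc <- read_sc_cells(path, tax, cfg), "K9")
  expect_equal(nrow(sc), 1L)
  expect_error(read_sc_cells(path, tax, analysis_config(strict = TRUE)),
               "K9", class = "atlasxref_validation_error")

  writeLines(c("cell_id\tregion\tcluster_id\tmarker_count",
               "c1\tCTX\tK1\t1"), path)
  expect_error(read_sc_cells(path, tax, cfg), "no cells in region",
               class = "atlasxref_empty_error")
})

test_that("structure roll-up maps substructures, is idempotent, excludes the unmapped", {
  map <- structure_map(c("MOB", "AOB", "AON"),
                       extra = c("AOBgr" = "AOB"))
  raw <- c("MOB-gl", "MOB", "AOBgr", "AONd1", "CTX", "AOB")
  rolled <- roll_up_structure(raw, map)
  expect_equal(rolled, c("MOB", "MOB", "AOB", "AON", NA, "AOB"))
  # idempotence on the mapped values
  expect_equal(roll_up_structure(rolled[!is.na(rolled)], map),
               rolled[!is.na(rolled)])
  # longest prefix wins when targets nest
  nested <- structure_map(c("AOB", "AOBX"))
  expect_equal(roll_up_structure("AOBX1", nested), "AOBX")
})

test_that("spatial reader rolls up, filters sections, and counts exclusions", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "st.tsv")
  map <- structure_map(c("MOB", "AOB", "AON"))

  writeLines(c("cell_id\tsection_id\tcluster_id\tstructure",
               "s1\t60\tK1\tMOB-gl",
               "s2\t62\tK1\tAOB",
               "s3\t64\tK2\tMOB",
               "s4\t60\tK2\tCTX"), path)
  cfg <- analysis_config(sections = c("60", "62"))
  st <- read_spatial_cells(path, map, cfg)
  expect_equal(st$cell_id, c("s1", "s2"))
  expect_equal(st$structure, c("MOB", "AOB"))
  excl <- attr(st, "excluded")
  expect_equal(unname(excl["off_section"]), 1L)
  expect_equal(unname(excl["unmapped_structure"]), 1L)
  expect_equal(nrow(st) + sum(excl), 4L)

  cfg_all <- analysis_config()
  st <- read_spatial_cells(path, map, cfg_all)
  expect_equal(nrow(st), 3L)

  writeLines(c("cell_id\tsection_id\tcluster_id\tstructure",
               "s1\t60\tK1\tCTX"), path)
  expect_error(read_spatial_cells(path, map, cfg_all),
               "no spatial cells", class = "atlasxref_empty_error")
})

test_that("writer and readers round-trip tables bit-identically", {
  dir <- withr::local_tempdir()

  tax_path <- file.path(dir, "tax.tsv")
  write_table(toy_taxonomy(), tax_path)
  expect_identical(read_taxonomy(tax_path), toy_taxonomy())

  sc_path <- file.path(dir, "sc.tsv")
  write_table(toy_sc_cells(), sc_path)
  sc2 <- read_sc_cells(sc_path, toy_taxonomy(), analysis_config())
  expect_identical(`attr<-`(sc2, "excluded", NULL), toy_sc_cells())

  # prevalence schema contract and fraction precision survive a round trip
  cfg <- analysis_config()
  prev <- cluster_prevalence(toy_sc_cells(),
                             filter_marker_positive(toy_sc_cells(), cfg),
                             toy_taxonomy(), cfg)
  prev_path <- file.path(dir, "prev.tsv")
  write_table(prev, prev_path)
  reread <- utils::read.delim(prev_path)
  expect_identical(names(reread),
                   c("cluster_id", "nt_class", "n_total", "n_pos",
                     "fraction", "ci_low", "ci_high"))
  expect_equal(reread$fraction, prev$fraction, tolerance = 1e-12)
  expect_equal(reread$ci_high, prev$ci_high, tolerance = 1e-12)

  # degenerate case: empty table writes a header-only file
  empty_path <- file.path(dir, "empty.tsv")
  write_table(toy_taxonomy()[0, ], empty_path)
  expect_equal(readLines(empty_path), "cluster_id\tcluster_label\tnt_class")
})

test_that("analysis configuration validates its knobs and reads from YAML", {
  expect_error(analysis_config(tau = 0), "tau",
               class = "atlasxref_validation_error")
  expect_error(analysis_config(structures = character(0)), "structures",
               class = "atlasxref_validation_error")
  expect_error(analysis_config(conf_level = 1), "conf_level",
               class = "atlasxref_validation_error")

  dir <- withr::local_tempdir()
  path <- file.path(dir, "cfg.yaml")
  writeLines(c("marker: Ghsr", "region: OLF", "tau: 2",
               "sections: ['60', '62']",
               "structures: [MOB, AOB]", "strict: false"), path)
  cfg <- read_config(path)
  expect_s3_class(cfg, "analysis_config")
  expect_equal(cfg$tau, 2L)
  expect_equal(cfg$sections, c("60", "62"))
  expect_false(cfg$strict)
})
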