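Package: atlasxref
Title: Cross-Referencing Single-Cell and Spatial Transcriptomics Atlases for
    Marker-Positive Cell Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies marker-gene-positive cells in a microdissected
    single-cell RNA-seq region, estimates per-cluster marker-positive
    prevalence with Jeffreys binomial intervals, summarises the
    neurotransmitter-class composition of the positive population, and
    imputes expected marker-positive cell counts per anatomical structure
    from spatial-transcriptomics (MERFISH-style) cell tables annotated with
    CCFv3 structure acronyms. Ships a seeded synthetic paired-atlas
    generator with closed-form ground truth so the whole pipeline is
    verifiable without any atlas download.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
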