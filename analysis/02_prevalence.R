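#!/usr/bin/env Rscript
# Step 2: stage-1 analysis on the simulated atlas — filter the dissection
# region to marker-positive cells, estimate each cluster's marker-positive
# fraction with a 95% Jeffreys interval, and summarise the
# neurotransmitter-class composition of the positive population.

library(atlasxref)

cfg <- analysis_config(marker = "Ghsr", region = "OLF", tau = 1)
tax <- read_taxonomy("results/data/taxonomy.tsv")
sc <- read_sc_cells("results/data/sc_cells.tsv", tax, cfg)

positives <- filter_marker_positive(sc, cfg)
prevalence <- cluster_prevalence(sc, positives, tax, cfg)
composition <- class_composition(positives, tax)

write_table(prevalence, "results/prevalence.tsv")
comp_out <- composition
comp_out$N_pos <- attr(composition, "N_pos")
write_table(comp_out, "results/composition.tsv")

message(nrow(positives), " of ", nrow(sc), " cells are marker-positive")
message("per-cluster prevalence:")
print(prevalence)
message("class composition of the positive population (%):")
print(transform(composition, pct = round(pct, 1)))
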