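#!/usr/bin/env Rscript
# Step 3: stage-2 analysis — carry the per-cluster marker-positive fractions
# into the spatial table, tabulate the relevant clusters by anatomical
# structure, and impute the expected number of marker-positive cells per
# structure and neurotransmitter class.

library(atlasxref)

cfg <- analysis_config(marker = "Ghsr", region = "OLF", tau = 1)
tax <- read_taxonomy("results/data/taxonomy.tsv")
prevalence <- utils::read.delim("results/prevalence.tsv",
                                colClasses = c(cluster_id = "character"))
st <- read_spatial_cells("results/data/spatial_cells.tsv",
                         structure_map(cfg$structures), cfg)

relevant <- select_relevant_clusters(prevalence, cfg$min_npos)
counts <- tabulate_structure_clusters(st, relevant,
                                      known = prevalence$cluster_id,
                                      strict = cfg$strict)
report <- impute_expected_counts(counts, prevalence, tax)

write_table(report$by_class, "results/imputation.tsv")
message(length(relevant), " relevant cluster(s); ",
        sum(counts$n), " spatial cells tabulated")
print(report)

# compare against the generator's closed-form truth
gt <- jsonlite::read_json("results/data/ground_truth.json",
                          simplifyVector = TRUE)
cmp <- merge(report$structures, gt$structures, by = "structure")
message("imputed vs true expected positives:")
print(cmp[, c("structure", "expected_pos", "true_expected_pos")])
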