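#!/usr/bin/env Rscript
# Step 2 -- build the model-ready analysis table.
#
# Reads the four raw tables written by step 1, aggregates leaf damage to a
# tree-level response, joins site covariates to trees and standardizes all
# predictors (climate and soil over sites, foliar chemistry over trees;
# quadratic climate terms as squares of the standardized linear terms).
# Writes one row per tree to results/analysis_table.csv.
source("analysis/00_common.R")

raw <- read_dataset_csv(DATA_DIR)
d <- prepare_model_data(raw$sites, raw$soil, raw$trees, raw$leaves)

out <- file.path(RESULTS_DIR, "analysis_table.csv")
write.csv(d$analysis_table, out, row.names = FALSE)

cat("analysis table: ", nrow(d$analysis_table), " trees x ",
    ncol(d$analysis_table), " columns -> ", out, "\n", sep = "")
cat("tree-level damage: mean ", sprintf("%.4f", mean(d$y_damage)),
    ", range ", sprintf("%.4f-%.4f", min(d$y_damage), max(d$y_damage)), "\n",
    sep = "")
cat("model dimensions: ", length(d$par_names), " parameters over ",
    nrow(d$sites), " sites / ", nrow(d$trees), " trees\n", sep = "")
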