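# Shared settings for the analysis drivers. Every script can be run on its
# own from the repository root; later steps regenerate what they need from
# the seeds below, so results are reproducible end to end.
library(herbcascade)

ANALYSIS_SEED <- 20L          # dataset realization
FIT_SEED <- 2020L             # chain seeds (FIT_SEED + 1:3)
RESULTS_DIR <- "results"
DATA_DIR <- file.path(RESULTS_DIR, "data")

dir.create(DATA_DIR, recursive = TRUE, showWarnings = FALSE)

analysis_dataset <- function() {
  generate_dataset(landscape_config(seed = ANALYSIS_SEED))
}

analysis_model_data <- function(ds = analysis_dataset()) {
  prepare_model_data(ds$sites, ds$soil, ds$trees, ds$leaves)
}

analysis_fit <- function(d = analysis_model_data()) {
  draws_file <- file.path(RESULTS_DIR, "draws.csv")
  if (file.exists(draws_file)) {
    message("reusing ", draws_file)
    read_draws_csv(draws_file)
  } else {
    fit <- run_mcmc(d, desk_schedule(seed = FIT_SEED))
    write_draws_csv(fit, draws_file)
    fit
  }
}
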