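#!/usr/bin/env Rscript
# Step 3 -- sample the joint posterior.
#
# Fits the three-tier model with the desk schedule (3 chains x 20000
# iterations, half burn-in, thinning 10 -> 3000 retained joint draws) using
# the package's compiled Metropolis-within-Gibbs sampler. Draws go to
# results/draws.csv; delete that file to force a refit.
source("analysis/00_common.R")

d <- analysis_model_data()
fit <- analysis_fit(d)

cat("retained draws: ", prod(dim(fit$draws)[1:2]), " over ",
    dim(fit$draws)[3], " parameters\n", sep = "")
sched <- fit$schedule
cat(sprintf("schedule: %d chains x %d iterations, burn-in %.0f%%, thin %d\n",
            sched$n_chains, sched$n_iterations, 100 * sched$burn_in,
            sched$thinning))
cat("draws stored in ", file.path(RESULTS_DIR, "draws.csv"), "\n", sep = "")
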