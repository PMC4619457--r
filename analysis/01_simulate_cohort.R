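#!/usr/bin/env Rscript
# Step 1: simulate the study cohort.
#
# Generates a synthetic cohort of 1,132 ACEI starters (the size of the
# validation cohort the package is modelled on) with the default generative
# parameters: latent ADRs driving switching and stopping, incomplete GP
# recording, background respiratory events, and censoring by death or
# moving. Writes the three pipeline inputs plus the latent ground truth
# under results/cohort/.

library(adrproxy)

seed <- 1132L
params <- cohort_params()          # defaults: n = 1132, 2000-2011 window
co <- generate_cohort(params, seed = seed)
paths <- write_cohort(co, "results/cohort")

cat("simulated", nrow(co$followup), "patients,",
    nrow(co$dispensing), "dispensings,",
    nrow(co$gp_events), "coded GP events (seed", seed, ")\n")
cat("latent ADR prevalence:",
    sprintf("%.1f%%", 100 * mean(co$ground_truth$has_adr)), "\n")
cat("exit reasons:\n")
print(table(co$followup$exit_reason))
cat("files written:\n")
cat(paste(" ", paths, collapse = "\n"), "\n")
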