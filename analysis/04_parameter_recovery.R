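#!/usr/bin/env Rscript
# Step 4: parameter recovery at scale.
#
# Simulates 20,000 patients under the default generative parameters and
# compares the pipeline's empirical PPVs against the generator's
# closed-form expected values, group by group and level by level. The gap
# between the two is reported in binomial standard errors. Writes
# results/parameter_recovery.csv.

library(adrproxy)

params <- cohort_params(n_patients = 20000L)
co <- generate_cohort(params, seed = 20000L)
pat <- classify_patterns(co$dispensing, co$followup, gap_days = 180)
adj <- adjudicate_cohort(pat, co$gp_events)
cts <- tabulate_validation(pat, adj)

rows <- list()
for (g in c("SWITCH_ARB", "SWITCH_OTHER", "STOP", "TOTAL_DISCONTINUATION")) {
  for (lv in ascertainment_levels()) {
    e <- ppv(cts, g, lv)
    ex <- expected_ppv(params, g, lv, gap_days = 180)
    se <- sqrt(ex * (1 - ex) / e$denominator)
    rows[[length(rows) + 1L]] <- data.frame(
      group = g, level = lv, n_group = e$denominator,
      empirical_pct = round(100 * e$estimate, 2),
      expected_pct = round(100 * ex, 2),
      z = round((e$estimate - ex) / se, 2))
  }
}
tab <- do.call(rbind, rows)
dir.create("results", showWarnings = FALSE)
utils::write.csv(tab, "results/parameter_recovery.csv", row.names = FALSE)

cat("empirical vs closed-form PPVs on 20,000 simulated patients",
    "(180-day gap)\n")
print(tab, row.names = FALSE)
cat(sprintf("largest absolute deviation: %.2f standard errors\n",
            max(abs(tab$z))))
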