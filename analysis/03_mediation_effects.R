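#!/usr/bin/env Rscript
# The main analysis: interventional disparity direct and indirect effects of
# low SES on death or ADL dependency at 3 months, decomposed through the
# four mediator blocks, with multiple imputation of severity and bootstrap
# standard errors. Desk-scale settings (documented in the methods
# vignette): m = 5 imputations, B = 50 bootstrap replicates with 50
# simulation draws each and exposure-by-mediator interactions, against the
# registry analysis settings of m = 45, B = 1,000, 200 draws with the full
# interaction set. Point estimates use the full 200 draws. About 25
# minutes on one CPU.
# Writes results/table3_low_vs_{mid,high}.csv and effect JSON files.

library(intervmed)

seed <- 20260924
tab <- read_cohort("results/cohort.csv", strict = FALSE)
tab <- complete_case_filter(tab)

for (ctr in c("mid", "high")) {
  cat(sprintf("\n== low vs %s SES ==\n", ctr))
  eff <- mi_analysis(tab, ctr, m = 5, B = 50, n_sim = 200, n_sim_boot = 50,
                     seed = seed, interactions = "exposure_only")
  t3 <- make_table3(eff)
  write.csv(t3, sprintf("results/table3_low_vs_%s.csv", ctr), row.names = FALSE)
  effect_set_json(eff, sprintf("results/effects_low_vs_%s.json", ctr))
  print(t3[, c("label", "estimate", "p", "pct_of_total")], row.names = FALSE)
}
cat("\nEnumerated true effects of the generating configuration:\n")
print(true_effects(default_dgp(), "mid"))
print(true_effects(default_dgp(), "high"))
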