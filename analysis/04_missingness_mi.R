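#!/usr/bin/env Rscript
# Missing-data experiment: does multiple imputation of the severity
# mediator remove the complete-case bias induced by the missing-at-random
# mechanism (missingness concentrated among patients without reperfusion
# therapy or stroke-unit care)? Twenty replicated cohorts; for each, the
# severity prevalence from (a) the complete cases and (b) the pooled
# imputations is compared with the pre-missingness truth.
# Writes results/mi_experiment.csv.

library(intervmed)

dgp <- default_dgp()
res <- do.call(rbind, lapply(1:20, function(i) {
  tab <- generate_cohort(dgp, 4000, seed = 7000 + i)
  truth <- mean(tab$severe)
  tabm <- inject_missingness(tab, missingness_config(), derive_seed(7000 + i, "m"))
  cc <- mean(tabm$severe, na.rm = TRUE)
  imps <- impute_severity(tabm, m = 10, seed = 8000 + i, interactions = "none")
  pooled <- mean(vapply(imps, function(t) mean(t$severe), numeric(1)))
  data.frame(replicate = i, truth = truth, complete_case = cc, pooled_mi = pooled,
             cc_abs_error = abs(cc - truth), mi_abs_error = abs(pooled - truth))
}))
dir.create("results", showWarnings = FALSE)
write.csv(res, "results/mi_experiment.csv", row.names = FALSE)
print(res, row.names = FALSE, digits = 3)
cat(sprintf("\nMI closer to truth in %d of 20 replicates (mean |error|: CC %.4f vs MI %.4f)\n",
            sum(res$mi_abs_error < res$cc_abs_error),
            mean(res$cc_abs_error), mean(res$mi_abs_error)))
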