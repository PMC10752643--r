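#!/usr/bin/env Rscript
# Calibrate the synthetic-registry generator to the published national
# stroke-register cohort characteristics (inst/extdata/registry_targets.csv):
# solve, by exact enumeration, the per-SES-group log-odds offsets of every
# structural equation so that the implied group prevalences of each mediator
# and of the outcome hit their targets. Prints the frozen constant block in
# R/dgp.R (DGP_SES_OFFSETS) and writes the calibrated prevalence check to
# results/calibration_check.csv.
#
# This script only needs rerunning if the structural slopes (DGP_SLOPES) or
# the targets change.

library(intervmed)

targets_path <- system.file("extdata", "registry_targets.csv", package = "intervmed")
tg <- read.csv(targets_path, check.names = FALSE)
vars <- c(default_ordering()$mediators, "outcome")
targets <- as.matrix(tg[match(vars, tg$variable), c("pct_low", "pct_mid", "pct_high")]) / 100
dimnames(targets) <- list(vars, c("low", "mid", "high"))

cat("Calibrating SES offsets by enumeration ...\n")
t0 <- Sys.time()
cal <- calibrate_dgp_offsets(default_dgp(), targets)
cat(sprintf("done in %.1f s\n", as.numeric(Sys.time() - t0, units = "secs")))

cat("\nPaste into R/dgp.R:\n\nDGP_SES_OFFSETS <- list(\n")
rows <- apply(cal$offsets, 1, function(o)
  sprintf("c(low = %.6f, mid = %.6f, high = %.6f)", o[1], o[2], o[3]))
cat(paste(sprintf("  %-17s = %s", rownames(cal$offsets), rows), collapse = ",\n"),
    "\n)\n\n")

imp <- dgp_implied_prevalences(cal$dgp)
chk <- data.frame(variable = rownames(imp$prevalences),
                  round(100 * imp$prevalences, 2),
                  target_low = 100 * targets[, "low"],
                  target_mid = 100 * targets[, "mid"],
                  target_high = 100 * targets[, "high"])
dir.create("results", showWarnings = FALSE)
write.csv(chk, "results/calibration_check.csv", row.names = FALSE)
print(chk, row.names = FALSE)
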