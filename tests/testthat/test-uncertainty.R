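# complete-case filtering, bootstrap, multiple imputation, Rubin pooling

test_that("complete-case filtering drops the right rows and reports", {
  tab <- sim_cohort(10, seed = 61)
  filtered <- complete_case_filter(tab)
  attr(filtered, "filter_report") <- NULL
  expect_identical(as.data.frame(filtered), as.data.frame(tab))
  df <- as.data.frame(tab)
  df$diabetes[c(3, 8)] <- NA
  df$severe[c(1, 5)] <- NA
  raw <- cohort_table(df, strict = FALSE)
  out <- complete_case_filter(raw)
  expect_equal(nrow(out), 8)
  expect_equal(sum(is.na(out$severe)), 2) # severity missingness is retained
  rep <- attr(out, "filter_report")
  expect_equal(rep$n_dropped, 2)
  expect_equal(unname(rep$missing_by_variable["diabetes"]), 2L)
})

test_that("Rubin pooling reproduces the hand-worked example", {
  p <- pool_rubin(c(1, 2, 3), c(1, 1, 1))
  expect_equal(p$estimate, 2.0)
  expect_equal(p$B, 1.0)
  expect_equal(p$T, 1 + (1 + 1 / 3) * 1, tolerance = 1e-12) # 2.3333
  expect_equal(p$se, sqrt(7 / 3), tolerance = 1e-12)        # 1.5275
  # zero between-imputation variance: SE reduces to sqrt(W)
  p0 <- pool_rubin(c(1.5, 1.5, 1.5), c(0.04, 0.04, 0.04))
  expect_equal(p0$estimate, 1.5)
  expect_equal(p0$B, 0)
  expect_equal(p0$se, 0.2, tolerance = 1e-12)
  expect_gte(p$T, p$W)
  expect_error(pool_rubin(1:3, 1:2), "equal length")
  # single imputation passes through
  p1 <- pool_rubin(2, 0.25)
  expect_equal(p1$se, 0.5)
})

test_that("imputation is proper, deterministic, and a no-op without missingness", {
  tab <- sim_cohort(400, seed = 62)
  copies <- impute_severity(tab, m = 3, seed = 9)
  expect_length(copies, 3)
  for (cp in copies) expect_identical(as.data.frame(cp), as.data.frame(tab))
  tabm <- sim_cohort(800, seed = 63, missing_target = 0.42)
  imp1 <- impute_severity(tabm, m = 4, seed = 11, interactions = "none")
  imp2 <- impute_severity(tabm, m = 4, seed = 11, interactions = "none")
  for (i in 1:4) {
    expect_false(anyNA(imp1[[i]]$severe))
    expect_identical(imp1[[i]]$severe, imp2[[i]]$severe)
    # observed values untouched
    obs <- !is.na(tabm$severe)
    expect_identical(imp1[[i]]$severe[obs], tabm$severe[obs])
  }
  # different imputations actually differ
  expect_false(identical(imp1[[1]]$severe, imp1[[2]]$severe))
})

test_that("an over-rich imputation model falls back to main effects with a warning", {
  tabm <- sim_cohort(120, seed = 64, missing_target = 0.42)
  expect_warning(imp <- impute_severity(tabm, m = 2, seed = 3,
                                        interactions = "full"),
                 "falling back")
  expect_false(anyNA(imp[[1]]$severe))
})

test_that("bootstrap of a sample mean matches the closed-form standard error", {
  set.seed(71)
  df <- data.frame(x = rnorm(500))
  br <- bootstrap_effects(df, function(t) c(mean = mean(t$x)), B = 1000, seed = 5)
  expect_lt(abs(br$se[["mean"]] - 1 / sqrt(500)), 0.15 / sqrt(500))
  expect_equal(br$n_failed, 0L)
  # a constant statistic has zero bootstrap SE and a degenerate interval
  bc <- bootstrap_effects(df, function(t) c(k = 1.5), B = 50, seed = 6)
  expect_equal(bc$se[["k"]], 0)
  expect_equal(bc$ci_low[["k"]], bc$ci_high[["k"]])
  # wholesale failure is not silently tolerated
  expect_error(bootstrap_effects(df, function(t) {
    if (nrow(t) == length(unique(attr(t, "row.names"))) &&
        !anyDuplicated(t$x)) c(v = 1) else stop("boom")
  }, B = 20, seed = 7), "failure rate")
})

test_that("bootstrap mediation inference keeps the decomposition structure", {
  tab <- sim_cohort(900, seed = 72)
  bm <- bootstrap_mediation(tab, "mid", B = 40, n_sim = 60, n_sim_boot = 30,
                            seed = 15, interactions = "exposure_only")
  e <- setNames(bm$estimate, bm$effect)
  expect_equal(unname(e["direct"] + e["indirect_all"]), unname(e["total"]),
               tolerance = 1e-12)
  expect_true(all(bm$se > 0))
  expect_true(all(bm$ci_low <= bm$estimate & bm$estimate <= bm$ci_high))
  expect_equal(bm$pct_of_total[bm$effect == "total"], 100)
  reps <- attr(bm, "replicates")
  expect_equal(dim(reps), c(40, 8))
  # replicate-level additivity holds too (CRN within each replicate)
  expect_equal(reps[, "direct"] + reps[, "indirect_all"], reps[, "total"],
               tolerance = 1e-10)
})

test_that("MI at zero missingness reproduces the complete-data pipeline exactly", {
  tab <- sim_cohort(600, seed = 73)
  seed <- 21
  mi <- mi_analysis(tab, "mid", m = 3, B = 12, n_sim = 40, seed = seed,
                    interactions = "exposure_only", effects = "total")
  direct <- bootstrap_mediation(tab, "mid", B = 12, n_sim = 40,
                                seed = derive_seed(seed, "boot"),
                                sim_seed = derive_seed(seed, "sim"),
                                interactions = "exposure_only", effects = "total")
  expect_identical(mi$estimate, direct$estimate)
  expect_equal(mi$B_between, 0)
  expect_equal(mi$se, direct$se, tolerance = 1e-12)
})

test_that("MI under missingness pools across imputations with T >= W", {
  tabm <- sim_cohort(700, seed = 74, missing_target = 0.42)
  mi <- mi_analysis(tabm, "mid", m = 3, B = 10, n_sim = 30, seed = 5,
                    interactions = "exposure_only",
                    imputation_interactions = "none", effects = "total")
  expect_true(all(mi$T_total >= mi$W))
  expect_gt(mi$B_between[1], 0)
  expect_match(attr(mi, "settings")$provenance, "3 multiply imputed datasets")
  per <- attr(mi, "per_imputation")
  expect_equal(ncol(per$estimates), 3)
})
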