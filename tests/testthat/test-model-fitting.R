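# design construction, logistic fitting, odds-ratio presentation

test_that("design columns follow the coding contract", {
  tab <- sim_cohort(50, seed = 5)
  X <- build_design(tab, model_spec("outcome", c("ses", "sex", "age")))
  expect_identical(colnames(X), c("(Intercept)", "ses_mid", "ses_high",
                                  "sex_male", "age_c", "age_c2"))
  expect_equal(X[, "age_c2"], X[, "age_c"]^2)
  X2 <- build_design(tab, model_spec("outcome", c("ses", "sex", "age", "severe"),
                                     interactions = list(c("ses", "severe"))))
  expect_true(all(c("ses_mid:severe", "ses_high:severe") %in% colnames(X2)))
  expect_equal(X2[, "ses_mid:severe"], X2[, "ses_mid"] * X2[, "severe"])
})

test_that("the anticoagulant-reperfusion interaction is excluded from the full outcome model", {
  sp <- outcome_spec(interactions = "full")
  keys <- vapply(sp$interactions, function(p) paste(sort(p), collapse = ":"),
                 character(1))
  expect_false("anticoagulants:reperfusion" %in% keys)
  expect_true("anticoagulants:statins" %in% keys)   # other mediator pairs stay
  tab <- sim_cohort(400, seed = 6)
  X <- build_design(tab, sp)
  expect_false(any(grepl("^anticoagulants:reperfusion$|^reperfusion:anticoagulants$",
                         colnames(X))))
})

test_that("missing values in model variables are rejected with guidance", {
  tab <- sim_cohort(100, seed = 8, missing_target = 0.3)
  expect_error(build_design(tab, outcome_spec()), "impute_severity")
})

test_that("2x2 data recover the closed-form log odds ratio", {
  # exposure 1: 40 events / 100; exposure 0: 25 events / 100 -> OR = 2
  df <- data.frame(x = rep(c(1, 0), each = 100),
                   y = c(rep(1:0, c(40, 60)), rep(1:0, c(25, 75))))
  fit <- fit_logistic(df, model_spec("y", "x", exclusions = list()))
  expect_equal(unname(fit$coefficients["x"]), log(2), tolerance = 1e-8)
  expect_true(fit$converged)
  expect_false(fit$separation)
})

test_that("a null simulation yields small, non-significant coefficients", {
  set.seed(404)
  df <- data.frame(y = rbinom(10000, 1, 0.5), x1 = rnorm(10000),
                   x2 = rbinom(10000, 1, 0.3))
  fit <- fit_logistic(df, model_spec("y", c("x1", "x2"), exclusions = list()))
  z <- fit$coefficients[c("x1", "x2")] /
    sqrt(diag(fit$vcov)[c("x1", "x2")])
  expect_true(all(abs(z) < 3))
})

test_that("perfect separation is flagged and constant responses error", {
  df <- data.frame(x = rep(0:1, each = 20), y = rep(0:1, each = 20))
  fit <- fit_logistic(df, model_spec("y", "x", exclusions = list()))
  expect_true(fit$separation)
  dfc <- data.frame(x = rnorm(20), y = rep(1, 20))
  expect_error(fit_logistic(dfc, model_spec("y", "x", exclusions = list())),
               "degenerate")
})

test_that("aliased columns are dropped with a warning, or rejected on request", {
  df <- data.frame(y = rbinom(200, 1, 0.5), x1 = rnorm(200))
  df$x2 <- df$x1 # exact collinearity
  sp <- model_spec("y", c("x1", "x2"), exclusions = list())
  expect_warning(fit <- fit_logistic(df, sp), "aliased")
  expect_false("x2" %in% names(fit$coefficients))
  expect_error(fit_logistic(df, sp, allow_rank_deficient = FALSE), "rank deficient")
})

test_that("predicted risks follow the inverse logit and are monotone in severity", {
  m <- make_model("y", c("(Intercept)" = 0, x = 1))
  expect_equal(predict_risk(m, data.frame(x = c(0, 1, -1))),
               plogis(c(0, 1, -1)), tolerance = 1e-12)
  expect_equal(predict_risk(m, data.frame(x = 1)), 0.7310586, tolerance = 1e-6)
  tab <- sim_cohort(300, seed = 10)
  om <- fit_outcome_model(tab, interactions = "none")
  t0 <- as.data.frame(tab)
  t0$severe <- 0L
  t1 <- as.data.frame(tab)
  t1$severe <- 1L
  expect_true(om$coefficients["severe"] > 0)
  expect_true(all(predict_risk(om, t1) > predict_risk(om, t0)))
})

test_that("odds-ratio rows reproduce closed-form Wald intervals", {
  m <- make_model("y", c("(Intercept)" = 0, x = log(2), z = 0))
  m$vcov <- diag(c(0.05, 0.1, 0.1)^2)
  dimnames(m$vcov) <- list(names(m$coefficients), names(m$coefficients))
  tab <- or_table(list(m = m), data.frame(model = "m", term = c("x", "z"),
                                          label = c("x row", "z row")))
  expect_equal(tab$or_fmt, c("2.00", "1.00"))
  expect_equal(tab$ci_fmt, c("1.64-2.43", "0.82-1.22"))
  # negation presents the low-vs-other direction
  tneg <- or_table(list(m = m), data.frame(model = "m", term = "x",
                                           label = "neg", negate = TRUE))
  expect_equal(tneg$or, 0.5, tolerance = 1e-12)
})

test_that("relabeling the SES reference flips signs but not fit quality", {
  tab <- sim_cohort(2000, seed = 12)
  sp <- model_spec("outcome", c("ses", "sex", "age"))
  fit1 <- fit_logistic(tab, sp)
  swapped <- as.data.frame(tab)
  swapped$ses <- factor(c(low = "mid", mid = "low", high = "high")[as.character(swapped$ses)],
                        levels = c("low", "mid", "high"))
  fit2 <- fit_logistic(cohort_table(swapped), sp)
  expect_equal(fit1$deviance, fit2$deviance, tolerance = 1e-6)
  expect_equal(unname(fit2$coefficients["ses_mid"]),
               -unname(fit1$coefficients["ses_mid"]), tolerance = 1e-6)
})

test_that("sequential mediator models are chain-rule consistent with the data", {
  tab <- sim_cohort(20000, seed = 14)
  mm <- fit_sequential_mediator_models(tab, interactions = "full")
  # first model has no mediator predictors
  expect_false(any(default_ordering()$mediators %in%
                     unlist(strsplit(names(mm[[1]]$coefficients), ":"))))
  # ancestral sampling at each record's own SES level reproduces observed
  # mediator prevalences within 3 binomial SEs
  df <- as.data.frame(tab)
  drawn <- matrix(NA_real_, nrow(df), length(default_ordering()$mediators))
  colnames(drawn) <- default_ordering()$mediators
  set.seed(99)
  for (lv in c("low", "mid", "high")) {
    idx <- which(df$ses == lv)
    U <- matrix(runif(length(idx) * 11), length(idx), 11)
    scn <- scenario(lv, lv, "joint")
    drawn[idx, ] <- draw_mediators(mm, df[idx, c("sex", "age")], scn, U)
  }
  for (m in default_ordering()$mediators) {
    obs <- mean(df[[m]])
    se <- sqrt(obs * (1 - obs) / nrow(df))
    expect_lt(abs(mean(drawn[, m]) - obs), 3 * se + 0.003)
  }
})

test_that("coefficients converge to generating values on large simulated data", {
  dgp <- default_dgp()
  tab <- generate_cohort(dgp, 50000, seed = 17)
  # severity equation: fit the correctly specified model and compare
  sp <- model_spec("severe", c("ses", "sex", "age", "smoker", "diabetes",
                               "atrial_fib", "prev_stroke", "anticoagulants"),
                   exclusions = list())
  fit <- fit_logistic(tab, sp)
  eq <- dgp$mediator_eqs$severe
  for (nm in c("ses_mid", "ses_high", "sex_male", "age_c", "atrial_fib")) {
    se <- sqrt(fit$vcov[nm, nm])
    expect_lt(abs(fit$coefficients[nm] - eq[nm]), 3 * se)
  }
  # SES coefficients in the severity model are negative (low = reference,
  # and low SES carries the highest severity risk)
  expect_true(all(fit$coefficients[c("ses_mid", "ses_high")] < 0))
})
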