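# synthetic registry generator: determinism, calibration-consistency,
# missingness mechanism, ground-truth oracle properties

test_that("generation is deterministic and n = 0 yields an empty table", {
  dgp <- default_dgp()
  expect_equal(nrow(generate_cohort(dgp, 0, seed = 1)), 0)
  a <- generate_cohort(dgp, 300, seed = 7)
  b <- generate_cohort(dgp, 300, seed = 7)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- generate_cohort(dgp, 300, seed = 8)
  expect_false(identical(as.data.frame(a), as.data.frame(c)))
})

test_that("a flat DGP gives 50% outcome prevalence", {
  dgp <- default_dgp()
  for (m in names(dgp$mediator_eqs)) {
    dgp$mediator_eqs[[m]][] <- 0
  }
  dgp$outcome_eq[] <- 0
  tab <- generate_cohort(dgp, 10000, seed = 2)
  # binomial 99% bounds around expit(0) = 0.5
  expect_lt(abs(mean(tab$outcome) - 0.5), 2.58 * sqrt(0.25 / 10000))
})

test_that("empirical moments match the enumerated implied prevalences", {
  dgp <- default_dgp()
  imp <- dgp_implied_prevalences(dgp)
  tab <- generate_cohort(dgp, 50000, seed = 33)
  df <- as.data.frame(tab)
  # SES shares
  shares <- table(df$ses) / nrow(df)
  for (g in c("low", "mid", "high")) {
    se <- sqrt(dgp$ses_probs[g] * (1 - dgp$ses_probs[g]) / nrow(df))
    expect_lt(abs(shares[[g]] - dgp$ses_probs[[g]]), 3 * se)
  }
  for (g in c("low", "mid", "high")) {
    sub <- df[df$ses == g, ]
    for (v in c("severe", "outcome", "reperfusion", "antihypertensives")) {
      p <- imp$prevalences[v, g]
      se <- sqrt(p * (1 - p) / nrow(sub))
      expect_lt(abs(mean(sub[[v]]) - p), 3 * se)
    }
    # sex and age marginals
    pf <- dgp$sex_prob_by_ses[[g]]
    expect_lt(abs(mean(sub$sex == "female") - pf),
              3 * sqrt(pf * (1 - pf) / nrow(sub)))
    expect_lt(abs(mean(sub$age) - dgp$age_mean_by_ses[[g]]), 1.0)
  }
})

test_that("missingness injection hits its target and respects MAR structure", {
  tab <- sim_cohort(25000, seed = 41)
  cfg <- missingness_config()
  expect_identical(inject_missingness(tab, missingness_config(target = 0), seed = 1),
                   tab)
  m1 <- inject_missingness(tab, cfg, seed = 5)
  m2 <- inject_missingness(tab, cfg, seed = 5)
  expect_identical(as.data.frame(m1), as.data.frame(m2))
  frac <- mean(is.na(m1$severe))
  expect_lt(abs(frac - 0.418), 3 * sqrt(0.418 * 0.582 / 25000))
  # only severity is touched
  expect_identical(as.data.frame(m1)[setdiff(names(m1), "severe")],
                   as.data.frame(tab)[setdiff(names(tab), "severe")])
  # missingness concentrates among the non-reperfused and non-stroke-unit
  by_rep <- tapply(is.na(m1$severe), m1$reperfusion, mean)
  expect_gt(by_rep[["0"]], by_rep[["1"]])
  by_su <- tapply(is.na(m1$severe), m1$stroke_unit, mean)
  expect_gt(by_su[["0"]], by_su[["1"]])
  # mechanisms referencing severity itself are rejected up front
  expect_error(missingness_config(coef = c(severe = 1)), "MAR")
})

test_that("true effects vanish exactly when the corresponding paths are absent", {
  # no SES -> mediator paths: all indirect and dependence effects exactly 0
  eff <- effect_vec(true_effects(null_mediator_dgp(), "mid", n_age_nodes = 16))
  ind <- eff[grep("^indirect", names(eff))]
  expect_true(all(ind == 0))
  expect_gt(eff["direct"], 0)
  expect_identical(unname(eff["direct"]), unname(eff["total"]))
  # no mediator -> outcome paths: indirect effects 0, direct equals total
  dgp2 <- default_dgp()
  meds <- dgp2$ordering$mediators
  drop <- names(dgp2$outcome_eq)[vapply(strsplit(names(dgp2$outcome_eq), ":"),
                                        function(p) any(p %in% meds), logical(1))]
  dgp2$outcome_eq[drop] <- 0
  eff2 <- effect_vec(true_effects(dgp2, "high", n_age_nodes = 16))
  # two different mediator laws integrate the same constant outcome risk:
  # zero up to accumulated floating-point error of the 2^11-term sums
  expect_true(all(abs(eff2[grep("^indirect", names(eff2))]) < 1e-10))
  expect_equal(unname(eff2["direct"]), unname(eff2["total"]), tolerance = 1e-10)
})

test_that("true effects satisfy the estimator's additivity identities", {
  for (ctr in c("mid", "high")) {
    eff <- effect_vec(true_effects(default_dgp(), ctr, n_age_nodes = 32))
    expect_equal(unname(eff["direct"] + eff["indirect_all"]), unname(eff["total"]),
                 tolerance = 1e-10)
    blocks <- eff[paste0("indirect_", names(default_ordering()$blocks))]
    expect_equal(unname(sum(blocks) + eff["indirect_dependence"]),
                 unname(eff["indirect_all"]), tolerance = 1e-10)
  }
})

test_that("strengthening the SES-severity path increases the severity indirect effect", {
  vals <- vapply(c(0, 0.3, 0.6), function(delta) {
    dgp <- default_dgp()
    dgp$mediator_eqs$severe["ses_mid"] <- dgp$mediator_eqs$severe["ses_mid"] - delta
    effect_vec(true_effects(dgp, "mid", n_age_nodes = 16))[["indirect_severity"]]
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("DGP configurations round-trip through YAML", {
  dgp <- default_dgp()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_dgp_yaml(dgp, path)
  back <- read_dgp_yaml(path)
  expect_equal(back$ses_probs, dgp$ses_probs)
  expect_equal(back$mediator_eqs, dgp$mediator_eqs, tolerance = 1e-12)
  expect_equal(back$outcome_eq, dgp$outcome_eq, tolerance = 1e-12)
  tab1 <- generate_cohort(dgp, 100, seed = 3)
  tab2 <- generate_cohort(back, 100, seed = 3)
  expect_identical(as.data.frame(tab1), as.data.frame(tab2))
})

test_that("invalid configurations are rejected", {
  expect_error(dgp_config(c(0.5, 0.4, 0.2), rep(0.5, 3), rep(75, 3), rep(10, 3),
                          mediator_eqs = default_dgp()$mediator_eqs,
                          outcome_eq = default_dgp()$outcome_eq),
               "sum to 1")
  dgp <- default_dgp()
  # a mediator equation referencing a later variable violates the ordering
  eqs <- dgp$mediator_eqs
  eqs$smoker <- c(eqs$smoker, severe = 0.5)
  expect_error(dgp_config(dgp$ses_probs, dgp$sex_prob_by_ses,
                          dgp$age_mean_by_ses, dgp$age_sd_by_ses,
                          mediator_eqs = eqs, outcome_eq = dgp$outcome_eq),
               "earlier variables")
})
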