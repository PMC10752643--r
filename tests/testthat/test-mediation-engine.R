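# Monte-Carlo g-computation engine: draw mechanics, closed-form checks,
# oracle agreement, exact decomposition structure

one_mediator_models <- function() {
  list(
    mediator = make_model("m1", c("(Intercept)" = -0.4, ses_mid = -0.6,
                                  sex_male = 0.3, age_c = 0.02)),
    outcome = make_model("outcome", c("(Intercept)" = -1.2, ses_mid = -0.25,
                                      m1 = 0.9, sex_male = -0.1, age_c = 0.03))
  )
}

# independent oracle: explicit 4-term sums over the single binary mediator
one_mediator_truth <- function(rows) {
  p_m <- function(level, sex, age) {
    plogis(-0.4 - 0.6 * (level == "mid") + 0.3 * (sex == "male") +
             0.02 * (age - 70))
  }
  f <- function(level, m, sex, age) {
    plogis(-1.2 - 0.25 * (level == "mid") + 0.9 * m - 0.1 * (sex == "male") +
             0.03 * (age - 70))
  }
  R <- function(a_out, a_med) {
    mean(mapply(function(sex, age) {
      p <- p_m(a_med, sex, age)
      p * f(a_out, 1, sex, age) + (1 - p) * f(a_out, 0, sex, age)
    }, rows$sex, rows$age))
  }
  100 * c(total = R("low", "low") - R("mid", "mid"),
          direct = R("low", "mid") - R("mid", "mid"),
          indirect_all = R("low", "low") - R("low", "mid"))
}

test_that("enumeration matches the hand-computed one-mediator sums", {
  mods <- one_mediator_models()
  tab <- toy_low_table(c("female", "male", "male"), c(68, 79, 85))
  truth <- one_mediator_truth(tab)
  en <- effect_vec(enumerate_disparity_effects(mods$outcome, list(mods$mediator),
                                               tab, "mid", ordering1()))
  expect_equal(en[names(truth)], truth, tolerance = 1e-12)
  # single block: the block indirect is the whole indirect effect and the
  # dependence term is exactly zero
  expect_equal(unname(en["indirect_b1"]), unname(en["indirect_all"]),
               tolerance = 1e-12)
  expect_identical(unname(en["indirect_dependence"]), 0)
})

test_that("the simulation estimator converges to the enumeration oracle", {
  mods <- one_mediator_models()
  tab <- toy_low_table(rep(c("female", "male"), 10), seq(55, 92, length.out = 20))
  truth <- effect_vec(enumerate_disparity_effects(mods$outcome, list(mods$mediator),
                                                  tab, "mid", ordering1()))
  est <- estimate_disparity_effects(mods$outcome, list(mods$mediator), tab,
                                    "mid", n_sim = 2000, seed = 77,
                                    ordering = ordering1())
  for (i in seq_len(nrow(est))) {
    expect_lt(abs(est$estimate[i] - truth[[est$effect[i]]]),
              3 * est$mc_se[i] + 1e-10)
  }
  # Monte-Carlo error shrinks at the canonical square-root rate
  mcse <- vapply(c(100, 1600), function(ns) {
    e <- estimate_disparity_effects(mods$outcome, list(mods$mediator), tab,
                                    "mid", n_sim = ns, seed = 78,
                                    ordering = ordering1())
    e$mc_se[e$effect == "indirect_all"]
  }, numeric(1))
  expect_lt(mcse[2], mcse[1] / 2)
})

test_that("mediator draws follow the uniform-threshold rule", {
  # P(m1 = 1) = 0.3 at low source, 0.2 at mid source; uniform 0.25 sits
  # between the two thresholds
  m <- make_model("m1", c("(Intercept)" = qlogis(0.3),
                          ses_mid = qlogis(0.2) - qlogis(0.3)))
  rows <- toy_low_table("female", 70)
  U <- matrix(0.25, 1, 1)
  d_low <- draw_mediators(list(m), rows, scenario("low", "low", ordering = ordering1()), U)
  d_mid <- draw_mediators(list(m), rows, scenario("low", "mid", ordering = ordering1()), U)
  expect_identical(unname(d_low[1, 1]), 1L)
  expect_identical(unname(d_mid[1, 1]), 0L)
})

test_that("SES-free mediator laws give identical draws across source levels", {
  tab <- sim_cohort(400, seed = 51)
  mods <- dgp_models(null_mediator_dgp())
  rows <- as.data.frame(tab)[as.data.frame(tab)$ses == "low", c("sex", "age")]
  set.seed(1)
  U <- matrix(runif(nrow(rows) * 11), nrow(rows), 11)
  d1 <- draw_mediators(mods$mediators, rows, scenario("low", "low"), U)
  d2 <- draw_mediators(mods$mediators, rows, scenario("low", "high"), U)
  expect_identical(d1, d2)
})

test_that("block-independent draws keep block marginals but break cross-block dependence", {
  # two blocks; m2 depends strongly on m1
  ord <- mediator_ordering(list(b1 = "m1", b2 = "m2"))
  mods <- list(make_model("m1", c("(Intercept)" = -0.5)),
               make_model("m2", c("(Intercept)" = -1.5, m1 = 2.0)))
  rows <- toy_low_table(rep("female", 50000), rep(70, 50000))
  scn_joint <- scenario("low", "low", "joint", ordering = ord)
  scn_ind <- scenario("low", "low", "block_independent", ordering = ord)
  set.seed(5)
  U <- matrix(runif(50000 * 2), 50000, 2)
  V <- lapply(1:2, function(k) matrix(runif(50000 * 2), 50000, 2))
  dj <- draw_mediators(mods, rows, scn_joint, U)
  di <- draw_mediators(mods, rows, scn_ind, U, V)
  for (j in 1:2) {
    se <- sqrt(0.25 / 50000)
    expect_lt(abs(mean(dj[, j]) - mean(di[, j])), 4 * se)
  }
  expect_gt(cor(dj[, 1], dj[, 2]), 0.2)
  expect_lt(abs(cor(di[, 1], di[, 2])), 0.02)
})

test_that("standardized scenario risk matches the closed form", {
  mods <- one_mediator_models()
  tab <- toy_low_table(c("female", "male"), c(65, 80))
  p <- plogis(-0.4 + 0.3 * c(0, 1) + 0.02 * (c(65, 80) - 70))
  f1 <- plogis(-1.2 + 0.9 - 0.1 * c(0, 1) + 0.03 * (c(65, 80) - 70))
  f0 <- plogis(-1.2 - 0.1 * c(0, 1) + 0.03 * (c(65, 80) - 70))
  closed <- mean(p * f1 + (1 - p) * f0)
  scn <- scenario("low", "low", ordering = ordering1())
  r <- scenario_risk(mods$outcome, list(mods$mediator), tab, scn,
                     n_sim = 2000, seed = 3)
  mc_se <- sd(attr(r, "reps")) / sqrt(2000)
  expect_lt(abs(as.numeric(r) - closed), 3 * mc_se + 1e-10)
  # outcome model without mediator effects: identical risk whatever the source
  om0 <- make_model("outcome", c("(Intercept)" = -0.8, ses_mid = -0.3,
                                 sex_male = 0.1))
  r_low <- scenario_risk(om0, list(mods$mediator), tab, scn, n_sim = 50, seed = 4)
  r_mid <- scenario_risk(om0, list(mods$mediator), tab,
                         scenario("low", "mid", ordering = ordering1()),
                         n_sim = 50, seed = 4)
  expect_identical(as.numeric(r_low), as.numeric(r_mid))
})

test_that("scenario constructors validate their invariants", {
  expect_error(scenario("low", c(comorbidities = "low", severity = "mid",
                                 reperfusion = "low", stroke_unit = "low"),
                        "joint"),
               "joint coupling")
  m <- one_mediator_models()$mediator
  expect_error(draw_mediators(list(m), toy_low_table("female", 70),
                              scenario("low", "low", ordering = ordering1()),
                              matrix(0.5, 2, 1)),
               "rows x mediators")
  tab <- sim_cohort(30, seed = 1)
  empty <- cohort_table(as.data.frame(tab)[tab$ses != "low", ])
  mods <- dgp_models(default_dgp())
  expect_error(adjusted_total_association(mods$outcome, mods$mediators, empty,
                                          "mid", n_sim = 5, seed = 1),
               "empty standardization")
})

test_that("percent of total is the plain ratio and guards division by zero", {
  expect_equal(percent_of_total(2.2, 5.4), 100 * 2.2 / 5.4)
  expect_equal(percent_of_total(5.4, 5.4), 100)
  expect_equal(percent_of_total(0, 5.4), 0)
  expect_error(percent_of_total(1, 0), "zero")
})

test_that("adjusted total association recovers the enumerated truth on average", {
  dgp <- default_dgp()
  truth <- effect_vec(true_effects(dgp, "mid"))[["total"]]
  mods <- dgp_models(dgp)
  # true models, sampled standardization rows: estimates distribute around
  # the enumerated value
  ests <- vapply(1:20, function(i) {
    tab <- generate_cohort(dgp, 1500, seed = 500 + i)
    effect_vec(adjusted_total_association(mods$outcome, mods$mediators, tab,
                                          "mid", n_sim = 60,
                                          seed = 600 + i))[["total"]]
  }, numeric(1))
  expect_lt(abs(mean(ests) - truth), 3 * sd(ests) / sqrt(20))
})
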