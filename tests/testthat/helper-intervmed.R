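# shared fixtures, all generated in code

# bare model object with exact coefficients (term language of the package)
make_model <- function(response, coefs) {
  structure(list(coefficients = coefs, vcov = NULL,
                 spec = list(response = response), n = NA_integer_,
                 converged = TRUE, iterations = 0L, separation = FALSE,
                 deviance = NA_real_, aliased = character(0)),
            class = "fitted_model")
}

# default synthetic cohort, optionally with missing severity
sim_cohort <- function(n, seed, missing_target = 0) {
  tab <- generate_cohort(default_dgp(), n, seed)
  if (missing_target > 0) {
    tab <- inject_missingness(tab, missingness_config(target = missing_target),
                              derive_seed(seed, "miss"))
  }
  tab
}

# default DGP with all SES -> mediator paths removed (direct effect kept)
null_mediator_dgp <- function() {
  dgp <- default_dgp()
  for (m in names(dgp$mediator_eqs)) {
    dgp$mediator_eqs[[m]][c("ses_mid", "ses_high")] <- 0
  }
  dgp
}

# minimal standardization table: low-SES rows with given confounders
toy_low_table <- function(sex, age) {
  df <- data.frame(ses = factor("low", levels = c("low", "mid", "high")),
                   sex = factor(sex, levels = c("female", "male")), age = age)
  df
}

# one-block, one-mediator ordering for micro examples
ordering1 <- function() mediator_ordering(list(b1 = "m1"))

effect_vec <- function(es) stats::setNames(es$estimate, es$effect)

# data content only: drop container class and bookkeeping attributes
as_plain_df <- function(x) {
  d <- as.data.frame(x)
  attr(d, "provenance") <- NULL
  attr(d, "codebook") <- NULL
  attr(d, "filter_report") <- NULL
  class(d) <- "data.frame"
  d
}
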