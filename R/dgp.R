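# Synthetic stroke-registry data-generating process.
#
# A fully specified logistic DGP over the cohort variables: SES is drawn as a
# 3-level factor; sex and age (truncated normal) depend on SES; the eleven
# binary mediators are generated by ancestral sampling in the causal block
# order (each equation may depend on SES, sex, age and previously generated
# mediators, which induces within- and between-block dependence); the
# outcome is logistic in exposure, confounders and mediators; auxiliaries
# are generated from severity and acute care so they carry real information
# for missing-at-random imputation. Because every equation is logistic over
# binary mediators, all population quantities (prevalences, true
# interventional effects) are exactly enumerable.

# evaluate a named coefficient vector (term language of design.R) on rows
eval_lp <- function(coefs, data) {
  lp <- rep(0, nrow(data))
  units <- list()
  unit <- function(nm) {
    if (!is.null(units[[nm]])) return(units[[nm]])
    v <- switch(nm,
      "(Intercept)" = rep(1, nrow(data)),
      ses_mid = as.numeric(data$ses == "mid"),
      ses_high = as.numeric(data$ses == "high"),
      sex_male = as.numeric(data$sex == "male"),
      age_c = data$age - AGE_CENTER,
      age_c2 = (data$age - AGE_CENTER)^2,
      amb_no = as.numeric(data$aux_ambulance == "no"),
      amb_unknown = as.numeric(data$aux_ambulance == "unknown"),
      {
        if (startsWith(nm, "onset_")) {
          as.numeric(data$aux_onset_to_door == sub("^onset_", "", nm))
        } else {
          if (is.null(data[[nm]])) stop("unknown term: ", nm, call. = FALSE)
          as.numeric(data[[nm]])
        }
      })
    units[[nm]] <<- v
    v
  }
  for (nm in names(coefs)) {
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    col <- unit(parts[1])
    if (length(parts) > 1) for (p in parts[-1]) col <- col * unit(p)
    lp <- lp + coefs[[nm]] * col
  }
  lp
}

# SES-group log-odds offsets of every structural equation, calibrated by
# exact enumeration so the implied group prevalences match the published
# registry targets (see inst/extdata/registry_targets.csv and
# analysis/00_calibrate_dgp.R, which regenerates these constants).
DGP_SES_OFFSETS <- list(
  smoker            = c(low = -1.543500, mid = -1.841767, high = -2.832736),
  diabetes          = c(low = -1.463241, mid = -1.550592, high = -1.875594),
  atrial_fib        = c(low = -1.400337, mid = -1.462921, high = -1.466238),
  prev_stroke       = c(low = -1.934867, mid = -1.822314, high = -1.948069),
  antihypertensives = c(low =  0.221322, mid =  0.172793, high =  0.006389),
  statins           = c(low = -1.612133, mid = -1.513728, high = -1.572379),
  antiplatelets     = c(low = -1.245950, mid = -1.253851, high = -1.377907),
  anticoagulants    = c(low = -3.191082, mid = -2.951713, high = -2.952948),
  severe            = c(low = -1.160795, mid = -1.201348, high = -1.258437),
  reperfusion       = c(low = -2.202524, mid = -1.966401, high = -1.804029),
  stroke_unit       = c(low =  2.272516, mid =  2.336174, high =  2.379958),
  outcome           = c(low = -2.271644, mid = -2.490462, high = -2.689835)
)

# structural slopes shared across SES groups (log-odds per unit; age per
# year, centered at 70). Chosen as clinically plausible magnitudes: within-
# block comorbidity dependence is small and positive, anticoagulation is
# driven strongly by atrial fibrillation, reperfusion is more likely for
# severe strokes and less likely under anticoagulation, and severity
# dominates the outcome equation.
DGP_SLOPES <- list(
  smoker            = c(sex_male = 0.30, age_c = -0.045),
  diabetes          = c(sex_male = 0.25, age_c = 0.010, smoker = 0.20),
  atrial_fib        = c(sex_male = 0.15, age_c = 0.055, diabetes = 0.20),
  prev_stroke       = c(sex_male = 0.10, age_c = 0.030, diabetes = 0.25,
                        atrial_fib = 0.25),
  antihypertensives = c(age_c = 0.040, diabetes = 0.80, atrial_fib = 0.70,
                        prev_stroke = 0.40),
  statins           = c(sex_male = 0.20, age_c = -0.010, diabetes = 0.90,
                        prev_stroke = 0.60, antihypertensives = 0.50),
  antiplatelets     = c(age_c = 0.030, diabetes = 0.30, prev_stroke = 0.90,
                        antihypertensives = 0.40, atrial_fib = -0.30),
  anticoagulants    = c(age_c = 0.020, atrial_fib = 2.20, prev_stroke = 0.30,
                        antiplatelets = -0.80),
  severe            = c(sex_male = -0.10, age_c = 0.035, smoker = 0.10,
                        diabetes = 0.10, atrial_fib = 0.45, prev_stroke = 0.20,
                        anticoagulants = -0.20),
  reperfusion       = c(age_c = -0.025, severe = 1.10, anticoagulants = -0.90,
                        prev_stroke = -0.20),
  stroke_unit       = c(age_c = -0.010, severe = 0.30, reperfusion = 1.00),
  outcome           = c(sex_male = -0.10, age_c = 0.065, age_c2 = 0.0010,
                        smoker = 0.15, diabetes = 0.38, atrial_fib = 0.25,
                        prev_stroke = 0.33, antihypertensives = 0.05,
                        statins = -0.10, antiplatelets = -0.02,
                        anticoagulants = 0.05, severe = 2.15,
                        reperfusion = -0.60, stroke_unit = -0.07,
                        "severe:reperfusion" = -0.30)
)

dgp_equation <- function(offsets, slopes) {
  c(c("(Intercept)" = unname(offsets["low"]),
      ses_mid = unname(offsets["mid"] - offsets["low"]),
      ses_high = unname(offsets["high"] - offsets["low"])),
    slopes)
}

#' Construct a synthetic-registry configuration
#'
#' @param ses_probs probabilities of the low/mid/high SES groups (sum 1).
#' @param sex_prob_by_ses probability of female sex per SES group.
#' @param age_mean_by_ses,age_sd_by_ses truncated-normal age parameters
#'   (years) per SES group.
#' @param age_bounds truncation bounds for age.
#' @param mediator_eqs named list (causal order) of named log-odds
#'   coefficient vectors for the eleven mediators.
#' @param outcome_eq named log-odds coefficient vector for the outcome.
#' @param aux list of auxiliary-variable generation parameters.
#' @param ordering a [mediator_ordering()].
#' @return an object of class `dgp_config`.
#' @export
dgp_config <- function(ses_probs, sex_prob_by_ses, age_mean_by_ses,
                       age_sd_by_ses, age_bounds = c(18, 105),
                       mediator_eqs, outcome_eq, aux = default_aux_params(),
                       ordering = default_ordering()) {
  stopifnot(length(ses_probs) == 3, length(sex_prob_by_ses) == 3,
            length(age_mean_by_ses) == 3, length(age_sd_by_ses) == 3)
  if (abs(sum(ses_probs) - 1) > 1e-12) {
    stop("ses_probs must sum to 1 (within 1e-12)", call. = FALSE)
  }
  if (any(age_sd_by_ses <= 0)) stop("age_sd must be > 0", call. = FALSE)
  if (!identical(names(mediator_eqs), ordering$mediators)) {
    stop("mediator_eqs must be named by the mediators in causal order",
         call. = FALSE)
  }
  allowed_base <- c("(Intercept)", "ses_mid", "ses_high", "sex_male",
                    "age_c", "age_c2")
  for (k in seq_along(mediator_eqs)) {
    eq <- mediator_eqs[[k]]
    if (any(!is.finite(eq))) stop("non-finite coefficient in mediator equation ",
                                  names(mediator_eqs)[k], call. = FALSE)
    prec <- ordering$mediators[seq_len(k - 1)]
    used <- unlist(strsplit(names(eq), ":", fixed = TRUE))
    bad <- setdiff(used, c(allowed_base, prec))
    if (length(bad)) {
      stop(sprintf("equation for `%s` may only use earlier variables; illegal: %s",
                   names(mediator_eqs)[k], paste(bad, collapse = ", ")),
           call. = FALSE)
    }
  }
  if (any(!is.finite(outcome_eq))) stop("non-finite outcome coefficient", call. = FALSE)
  names(ses_probs) <- names(sex_prob_by_ses) <- SES_LEVELS
  names(age_mean_by_ses) <- names(age_sd_by_ses) <- SES_LEVELS
  structure(list(ses_probs = ses_probs, sex_prob_by_ses = sex_prob_by_ses,
                 age_mean_by_ses = age_mean_by_ses, age_sd_by_ses = age_sd_by_ses,
                 age_bounds = age_bounds, mediator_eqs = mediator_eqs,
                 outcome_eq = outcome_eq, aux = aux, ordering = ordering),
            class = "dgp_config")
}

default_aux_params <- function() {
  list(
    rls = c("(Intercept)" = -2.1, severe = 2.3, age_c = 0.015),
    ambulance_unknown = 0.04,
    ambulance_yes = c("(Intercept)" = 0.4, severe = 1.3, age_c = 0.012),
    onset_unknown = 0.08,
    onset_eta = c(severe = 0.7, reperfusion = 0.3, amb_yes = 1.0),
    onset_cutpoints = c(-0.9, -0.1, 0.4, 1.6)
  )
}

#' Default calibrated synthetic-registry configuration
#'
#' Fixed, versioned configuration whose enumerated SES-group shares and
#' within-group prevalences of the outcome and all mediators match the
#' published national stroke-register cohort characteristics shipped in
#' `inst/extdata/registry_targets.csv` (group shares within 1 percentage
#' point, prevalences within 3). Calibration solves each equation's SES
#' offsets by exact enumeration; `analysis/00_calibrate_dgp.R` regenerates
#' the frozen constants.
#'
#' @return a `dgp_config`.
#' @export
default_dgp <- function() {
  meds <- default_ordering()$mediators
  eqs <- lapply(meds, function(m) dgp_equation(DGP_SES_OFFSETS[[m]], DGP_SLOPES[[m]]))
  names(eqs) <- meds
  dgp_config(
    ses_probs = c(0.160, 0.711, 0.129),
    sex_prob_by_ses = c(0.601, 0.428, 0.361),
    age_mean_by_ses = c(80.5, 73.9, 70.3),
    age_sd_by_ses = c(10.7, 11.6, 12.5),
    mediator_eqs = eqs,
    outcome_eq = dgp_equation(DGP_SES_OFFSETS$outcome, DGP_SLOPES$outcome)
  )
}

#' Structural equations of a DGP as model objects
#'
#' Wraps the mediator and outcome equations of a `dgp_config` as
#' `fitted_model`-compatible objects (exact coefficients, no covariance), so
#' the estimation engine and the enumeration oracle can run on the true
#' generating law.
#'
#' @param dgp a `dgp_config`.
#' @return list with `outcome` (a model object) and `mediators` (ordered
#'   named list of model objects).
#' @export
dgp_models <- function(dgp) {
  as_model <- function(response, coefs) {
    structure(list(coefficients = coefs, vcov = NULL,
                   spec = list(response = response, terms = NULL),
                   n = NA_integer_, converged = TRUE, iterations = 0L,
                   separation = FALSE, deviance = NA_real_, aliased = character(0),
                   exact = TRUE),
              class = "fitted_model")
  }
  meds <- lapply(names(dgp$mediator_eqs), function(m) as_model(m, dgp$mediator_eqs[[m]]))
  names(meds) <- names(dgp$mediator_eqs)
  list(outcome = as_model("outcome", dgp$outcome_eq), mediators = meds)
}

rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Generate a synthetic cohort
#'
#' Ancestral sampling in DAG order: SES, then sex and age, then the eleven
#' mediators in causal block order, the outcome, and finally the three
#' auxiliary variables (driven by severity and acute care). Deterministic
#' given `seed`; the generated table has no missing values (use
#' [inject_missingness()] afterwards). Ages are rounded to two decimals so
#' cohorts round-trip bit-for-bit through the CSV writer.
#'
#' @param dgp a `dgp_config`.
#' @param n number of records (>= 0).
#' @param seed integer seed.
#' @return a `cohort_table` with provenance `"synthetic"`.
#' @export
generate_cohort <- function(dgp, n, seed) {
  stopifnot(inherits(dgp, "dgp_config"), n >= 0)
  if (n == 0) {
    df <- as.data.frame(stats::setNames(rep(list(character(0)), length(COHORT_COLUMNS)),
                                        COHORT_COLUMNS))
    return(cohort_table(df, provenance = "synthetic"))
  }
  with_seed(seed, {
    ses <- factor(sample(SES_LEVELS, n, replace = TRUE, prob = dgp$ses_probs),
                  levels = SES_LEVELS)
    pf <- dgp$sex_prob_by_ses[as.integer(ses)]
    sex <- factor(ifelse(stats::runif(n) < pf, "female", "male"),
                  levels = SEX_LEVELS)
    age <- round(rtruncnorm(n, dgp$age_mean_by_ses[as.integer(ses)],
                            dgp$age_sd_by_ses[as.integer(ses)],
                            dgp$age_bounds[1], dgp$age_bounds[2]), 2)
    df <- data.frame(ses = ses, sex = sex, age = age)
    for (m in names(dgp$mediator_eqs)) {
      p <- stats::plogis(eval_lp(dgp$mediator_eqs[[m]], df))
      df[[m]] <- as.integer(stats::runif(n) < p)
    }
    df$outcome <- as.integer(stats::runif(n) < stats::plogis(eval_lp(dgp$outcome_eq, df)))
    aux <- dgp$aux
    df$aux_rls_gt1 <- as.integer(stats::runif(n) < stats::plogis(eval_lp(aux$rls, df)))
    u_amb <- stats::runif(n)
    amb_yes <- stats::runif(n) < stats::plogis(eval_lp(aux$ambulance_yes, df))
    df$aux_ambulance <- factor(
      ifelse(u_amb < aux$ambulance_unknown, "unknown",
             ifelse(amb_yes, "yes", "no")), levels = AMBULANCE_LEVELS)
    eta <- aux$onset_eta["severe"] * df$severe +
      aux$onset_eta["reperfusion"] * df$reperfusion +
      aux$onset_eta["amb_yes"] * (df$aux_ambulance == "yes")
    u_on <- stats::runif(n)
    u_cat <- stats::runif(n)
    cum <- vapply(aux$onset_cutpoints, function(cp) stats::plogis(cp + eta),
                  numeric(n))
    cat_idx <- 1L + rowSums(u_cat > cum)
    df$aux_onset_to_door <- factor(
      ifelse(u_on < aux$onset_unknown, "unknown", ONSET_LEVELS[cat_idx]),
      levels = ONSET_LEVELS)
    cohort_table(df[, COHORT_COLUMNS], provenance = "synthetic")
  })
}

#' Configure the severity-missingness mechanism
#'
#' Logistic missingness model for the severity mediator using observed
#' variables only (missing at random by construction): by default,
#' missingness is much more likely for patients not receiving reperfusion
#' therapy and not treated in a stroke unit, with smaller contributions from
#' the auxiliaries, age and sex. The intercept is solved at injection time
#' so the expected missing fraction equals `target`.
#'
#' @param coef named log-odds coefficient vector (term language, no
#'   intercept); must not reference `severe` itself or the outcome.
#' @param target overall missing fraction in \[0, 1).
#' @return an object of class `missingness_config`.
#' @export
missingness_config <- function(
  coef = c(reperfusion = -1.1, stroke_unit = -0.9, sex_male = 0.10,
           age_c = 0.008, aux_rls_gt1 = -0.30, amb_no = 0.25,
           onset_unknown = 0.60),
  target = 0.418
) {
  used <- unlist(strsplit(names(coef), ":", fixed = TRUE))
  if ("severe" %in% used) {
    stop("missingness mechanism may not reference `severe` (would violate MAR)",
         call. = FALSE)
  }
  stopifnot(target >= 0, target < 1, all(is.finite(coef)))
  structure(list(coef = coef, target = target), class = "missingness_config")
}

#' Inject missing-at-random severity values
#'
#' Sets `severe` to missing according to the logistic mechanism in `cfg`,
#' with the intercept calibrated on the given table so the expected missing
#' fraction equals the configured target. All other fields are untouched;
#' deterministic given `seed`.
#'
#' @param table complete `cohort_table`.
#' @param cfg a [missingness_config()].
#' @param seed integer seed.
#' @return a `cohort_table` with missing severity values.
#' @export
inject_missingness <- function(table, cfg, seed) {
  stopifnot(inherits(table, "cohort_table"), inherits(cfg, "missingness_config"))
  if (anyNA(table$severe)) stop("table already has missing severity", call. = FALSE)
  if (cfg$target == 0 || nrow(table) == 0) return(table)
  lp <- eval_lp(cfg$coef, as.data.frame(table))
  f <- function(c0) mean(stats::plogis(c0 + lp)) - cfg$target
  c0 <- stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
  p_miss <- stats::plogis(c0 + lp)
  with_seed(seed, {
    miss <- stats::runif(nrow(table)) < p_miss
    table$severe[miss] <- NA_integer_
    table
  })
}

#' Serialize a DGP configuration to YAML
#' @param dgp a `dgp_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dgp_yaml <- function(dgp, path) {
  x <- unclass(dgp)
  x$ordering <- lapply(x$ordering$blocks, as.list)
  x$mediator_eqs <- lapply(x$mediator_eqs, as.list)
  x$outcome_eq <- as.list(x$outcome_eq)
  x$aux <- lapply(x$aux, function(a) if (is.numeric(a) && !is.null(names(a))) as.list(a) else a)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a DGP configuration from YAML
#' @param path YAML file written by [write_dgp_yaml()].
#' @return a `dgp_config`.
#' @export
read_dgp_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  num <- function(l) {
    v <- unlist(l)
    stats::setNames(as.numeric(v), names(v))
  }
  aux <- lapply(x$aux, function(a) if (is.list(a)) num(a) else unlist(a))
  dgp_config(
    ses_probs = num(x$ses_probs), sex_prob_by_ses = num(x$sex_prob_by_ses),
    age_mean_by_ses = num(x$age_mean_by_ses), age_sd_by_ses = num(x$age_sd_by_ses),
    age_bounds = num(x$age_bounds),
    mediator_eqs = lapply(x$mediator_eqs, num),
    outcome_eq = num(x$outcome_eq), aux = aux,
    ordering = mediator_ordering(lapply(x$ordering, unlist))
  )
}
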