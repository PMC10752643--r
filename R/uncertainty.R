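# Bootstrap standard errors, multiple imputation of the severity mediator,
# Rubin's-rules pooling, and complete-case filtering.

# fast subset of a validated cohort table (no re-validation)
cohort_subset <- function(table, idx) {
  df <- as.data.frame(table)[idx, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, provenance = attr(table, "provenance"),
            codebook = attr(table, "codebook"),
            class = c("cohort_table", "data.frame"))
}

#' Complete-case filter outside the severity mediator
#'
#' Drops records with a missing value in any variable except those in
#' `ignore` (default: `severe`, which is retained for multiple imputation).
#' The returned table carries a `filter_report` attribute with the number of
#' dropped records and per-variable missing counts.
#'
#' @param table a `cohort_table` (typically permissive/raw).
#' @param ignore variables whose missingness is tolerated.
#' @return filtered `cohort_table`.
#' @export
complete_case_filter <- function(table, ignore = "severe") {
  check_vars <- setdiff(COHORT_COLUMNS, ignore)
  df <- as.data.frame(table)
  na_by_var <- vapply(check_vars, function(v) sum(is.na(df[[v]])), integer(1))
  any_na <- rep(FALSE, nrow(df))
  for (v in check_vars) any_na <- any_na | is.na(df[[v]])
  keep <- !any_na
  out <- cohort_subset(table, keep)
  attr(out, "filter_report") <- list(n_in = nrow(df), n_out = sum(keep),
                                     n_dropped = sum(!keep),
                                     missing_by_variable = na_by_var[na_by_var > 0])
  out
}

#' Specification of the severity imputation model
#'
#' Logistic regression of the dichotomized severity indicator on all
#' analysis variables (exposure, confounders with age-squared, the ten other
#' mediators, the outcome) and the three auxiliary variables; in `"full"`
#' mode, all 2-way interactions among exposure, mediators and outcome except
#' the anticoagulant-reperfusion pair.
#'
#' @param ordering a [mediator_ordering()].
#' @param interactions `"full"` or `"none"`.
#' @return a `model_spec`.
#' @export
imputation_spec <- function(ordering = default_ordering(),
                            interactions = "full") {
  interactions <- match.arg(interactions, c("full", "none"))
  others <- setdiff(ordering$mediators, "severe")
  ints <- list()
  if (interactions == "full") {
    set <- c("ses", others, "outcome")
    for (i in seq_along(set)[-length(set)]) {
      for (j in seq((i + 1), length(set))) {
        ints <- c(ints, list(c(set[i], set[j])))
      }
    }
  }
  model_spec("severe", c("ses", "sex", "age", others, "outcome", AUX_VARS), ints)
}

#' Multiply impute the severity mediator
#'
#' Proper multiple imputation under missing-at-random: the imputation model
#' is fitted on the complete records; for each of the `m` datasets a
#' coefficient vector is drawn from the asymptotic normal approximation to
#' its posterior (mean = MLE, covariance = fitted covariance), missing
#' severity values are drawn Bernoulli from the resulting predicted
#' probabilities. The default `m = 45` follows the guidance that the number
#' of imputations should be at least the percentage of missing data (about
#' 42% here). If the full-interaction model shows separation or fails, an
#' interaction-free model is used with a warning.
#'
#' @param table `cohort_table` in which only `severe` is missing.
#' @param m number of imputed datasets.
#' @param seed integer seed (imputations are deterministic given it).
#' @param interactions `"full"` or `"none"`.
#' @param ordering a [mediator_ordering()].
#' @return list of `m` completed `cohort_table`s; attribute `model` holds
#'   the fitted imputation model.
#' @export
impute_severity <- function(table, m = 45, seed = 1L, interactions = "full",
                            ordering = default_ordering()) {
  stopifnot(inherits(table, "cohort_table"), m >= 1)
  for (v in setdiff(COHORT_COLUMNS, "severe")) {
    if (anyNA(table[[v]])) {
      stop("only `severe` may be missing when imputing; run complete_case_filter() first",
           call. = FALSE)
    }
  }
  miss <- is.na(table$severe)
  if (!any(miss)) return(rep(list(table), m))
  obs <- cohort_subset(table, !miss)
  fit <- tryCatch({
    f <- fit_logistic(obs, imputation_spec(ordering, interactions), quiet = TRUE)
    if (f$separation || !f$converged) stop("separation or non-convergence")
    f
  }, error = function(e) NULL)
  if (is.null(fit) && interactions != "none") {
    warning("full-interaction imputation model unstable; falling back to main effects",
            call. = FALSE)
    fit <- fit_logistic(obs, imputation_spec(ordering, "none"), quiet = TRUE)
  }
  miss_rows <- cohort_subset(table, miss) # `severe` is the response, not a predictor
  X <- build_design(miss_rows, fit$spec)
  X <- X[, names(fit$coefficients), drop = FALSE]
  b <- fit$coefficients
  V <- fit$vcov
  # draw from N(b, V): symmetric eigen square root is robust to the
  # near-singular covariances of rich interaction models
  ev <- eigen(V, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), length(b))
  out <- with_seed(seed, {
    lapply(seq_len(m), function(i) {
      beta_i <- b + drop(L %*% stats::rnorm(length(b)))
      p <- stats::plogis(drop(X %*% beta_i))
      filled <- table
      filled$severe[miss] <- as.integer(stats::runif(sum(miss)) < p)
      filled
    })
  })
  attr(out, "model") <- fit
  out
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Pooled estimate = mean of the per-imputation estimates; total variance
#' T = W + (1 + 1/m) B with W the mean within-imputation variance and B the
#' between-imputation variance of the estimates. Confidence intervals and
#' p-values use the normal reference — with registry-scale samples and
#' m = 45 the small-sample degrees-of-freedom correction is negligible.
#'
#' @param estimates numeric vector of per-imputation estimates.
#' @param variances numeric vector of per-imputation (squared-SE) variances.
#' @return list with `estimate`, `W`, `B`, `T`, `se`, `ci_low`, `ci_high`,
#'   `p`, `m`.
#' @export
pool_rubin <- function(estimates, variances) {
  if (length(estimates) != length(variances)) {
    stop("estimates and variances must have equal length", call. = FALSE)
  }
  m <- length(estimates)
  est <- mean(estimates)
  W <- mean(variances)
  B <- if (m >= 2) stats::var(estimates) else 0
  Tv <- W + (1 + 1 / m) * B
  se <- sqrt(Tv)
  z <- if (se > 0) est / se else Inf * sign(est)
  list(estimate = est, W = W, B = B, T = Tv, se = se,
       ci_low = est - 1.96 * se, ci_high = est + 1.96 * se,
       p = if (is.finite(z)) 2 * stats::pnorm(-abs(z)) else 0, m = m)
}

#' Nonparametric bootstrap of an arbitrary cohort statistic
#'
#' `B` resamples of records with replacement; `analysis` is re-run in full
#' on each resample. Standard errors are the standard deviation of the
#' successful replicate estimates; confidence intervals are Wald intervals
#' around the original-sample point estimate. Failed replicates are counted
#' and reported, and more than 10% failures is an error.
#'
#' @param table a `cohort_table`.
#' @param analysis function taking a `cohort_table` and returning a named
#'   numeric vector.
#' @param B number of bootstrap replicates (>= 2).
#' @param seed integer seed; replicate resampling seeds derive from it.
#' @return object of class `bootstrap_result`: `point`, `se`, `ci_low`,
#'   `ci_high`, `p`, `replicates` (B x effects), `n_failed`.
#' @export
bootstrap_effects <- function(table, analysis, B, seed = 1L) {
  stopifnot(B >= 2)
  point <- analysis(table)
  n <- nrow(table)
  reps <- matrix(NA_real_, B, length(point),
                 dimnames = list(NULL, names(point)))
  n_failed <- 0L
  for (b in seq_len(B)) {
    idx <- with_seed(derive_seed(seed, paste0("resample", b)),
                     sample.int(n, n, replace = TRUE))
    val <- tryCatch(analysis(cohort_subset(table, idx)), error = function(e) NULL)
    if (is.null(val)) n_failed <- n_failed + 1L else reps[b, ] <- val[names(point)]
  }
  if (n_failed > 0.1 * B) {
    stop(sprintf("bootstrap failure rate too high: %d of %d replicates failed",
                 n_failed, B), call. = FALSE)
  }
  se <- apply(reps, 2, stats::sd, na.rm = TRUE)
  z <- ifelse(se > 0, point / se, Inf * sign(point))
  structure(list(point = point, se = se,
                 ci_low = point - 1.96 * se, ci_high = point + 1.96 * se,
                 p = ifelse(is.finite(z), 2 * stats::pnorm(-abs(z)),
                            ifelse(point == 0, 1, 0)),
                 replicates = reps, B = B, seed = seed, n_failed = n_failed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Bootstrap result: B = %d (%d failed)\n", x$B, x$n_failed))
  print(data.frame(point = x$point, se = x$se, ci_low = x$ci_low,
                   ci_high = x$ci_high, p = x$p))
  invisible(x)
}

# fitted models for the mediation pipeline from prebuilt design matrices;
# warm-started replicate refits use a looser IRLS tolerance (coefficient
# noise well below bootstrap noise)
fit_mediation_models <- function(designs, idx = NULL, warm = NULL) {
  ctrl <- if (is.null(warm)) {
    stats::glm.control(epsilon = 1e-8, maxit = 100)
  } else {
    stats::glm.control(epsilon = 1e-6, maxit = 30)
  }
  lapply(designs, function(d) {
    X <- d$X
    y <- d$y
    if (!is.null(idx)) {
      X <- X[idx, , drop = FALSE]
      y <- y[idx]
    }
    fit_logistic_xy(X, y, d$spec, allow_rank_deficient = TRUE,
                    warm_start = warm[[d$spec$response]], quiet = TRUE,
                    control = ctrl)
  })
}

#' Bootstrap inference for the disparity decomposition
#'
#' Optimized bootstrap of the full mediation pipeline: every replicate
#' resamples records, refits the outcome and all sequential mediator models
#' (warm-started at the original estimates; aliased columns dropped
#' silently), and re-estimates the effects by Monte-Carlo g-computation with
#' `n_sim_boot` repetitions. Standard errors are replicate standard
#' deviations; intervals are Wald intervals around the original-sample point
#' estimates; percent-of-total intervals come from the replicate ratios.
#'
#' @inheritParams estimate_disparity_effects
#' @param B number of bootstrap replicates (default 1000).
#' @param n_sim_boot simulation repetitions per replicate (defaults to
#'   `n_sim`; can be reduced for desk-scale runs).
#' @param interactions interaction mode for the fitted models.
#' @param sim_seed seed of the point-estimate simulation stream.
#' @param effects `"all"` or `"total"` (total association only, cheaper).
#' @return an `effect_set` with columns `estimate`, `se`, `ci_low`,
#'   `ci_high`, `p`, `pct_of_total`, `pct_ci_low`, `pct_ci_high`; replicate
#'   estimates in attribute `replicates`.
#' @export
bootstrap_mediation <- function(table, contrast, B = 1000, n_sim = 200,
                                n_sim_boot = n_sim, seed = 1L,
                                interactions = "full",
                                ordering = default_ordering(),
                                standardization = "low", effects = "all",
                                sim_seed = derive_seed(seed, "sim")) {
  stopifnot(B >= 2)
  effects <- match.arg(effects, c("all", "total"))
  which_evals <- if (effects == "all") "all" else "total"
  specs <- c(list(outcome_spec(ordering, interactions)),
             sequential_specs(ordering, interactions))
  designs <- lapply(specs, function(sp) {
    list(X = build_design(table, sp), y = response_vector(table, sp), spec = sp)
  })
  fits <- fit_mediation_models(designs)
  names(fits) <- c("outcome", ordering$mediators)
  warm <- lapply(fits, `[[`, "coefficients")
  names(warm) <- vapply(specs, `[[`, character(1), "response")

  df <- as.data.frame(table)
  eval_effects <- function(models, rows, nsim, sd_seed) {
    R <- simulate_evaluations(models$outcome, models$mediators, rows, contrast,
                              nsim, sd_seed, ordering, which = which_evals)
    Ebar <- colMeans(R)
    if (effects == "all") {
      effects_from_evals(Ebar, ordering)
    } else {
      c(total = 100 * unname(Ebar["joint_low_out_low"] -
                               Ebar["joint_comp_out_comp"]))
    }
  }
  models0 <- list(outcome = fits$outcome, mediators = fits[ordering$mediators])
  rows0 <- standardization_rows(table, standardization)
  point <- eval_effects(models0, rows0, n_sim, sim_seed)

  n <- nrow(df)
  ses_v <- df$ses
  sex_v <- df$sex
  age_v <- df$age
  reps <- matrix(NA_real_, B, length(point), dimnames = list(NULL, names(point)))
  n_failed <- 0L
  for (b in seq_len(B)) {
    rep_seed <- derive_seed(seed, paste0("rep", b))
    idx <- with_seed(rep_seed, sample.int(n, n, replace = TRUE))
    val <- tryCatch({
      fb <- fit_mediation_models(designs, idx = idx, warm = warm)
      names(fb) <- names(fits)
      sel <- if (standardization == "low") idx[ses_v[idx] == "low"] else idx
      if (length(sel) == 0) stop("empty low-SES stratum in resample")
      rows_b <- data.frame(sex = sex_v[sel], age = age_v[sel])
      eval_effects(list(outcome = fb$outcome, mediators = fb[ordering$mediators]),
                   rows_b, n_sim_boot, derive_seed(rep_seed, "sim"))
    }, error = function(e) NULL)
    if (is.null(val)) n_failed <- n_failed + 1L else reps[b, ] <- val[names(point)]
  }
  if (n_failed > 0.1 * B) {
    stop(sprintf("bootstrap failure rate too high: %d of %d replicates failed",
                 n_failed, B), call. = FALSE)
  }
  se <- apply(reps, 2, stats::sd, na.rm = TRUE)
  z <- ifelse(se > 0, point / se, Inf * sign(point))
  out <- new_effect_set(point, contrast,
                        settings = list(method = "simulation+bootstrap",
                                        n_sim = n_sim, n_sim_boot = n_sim_boot,
                                        B = B, seed = seed, sim_seed = sim_seed,
                                        interactions = interactions,
                                        standardization = standardization,
                                        n_failed = n_failed))
  out$se <- unname(se)
  out$ci_low <- unname(point - 1.96 * se)
  out$ci_high <- unname(point + 1.96 * se)
  out$p <- unname(ifelse(is.finite(z), 2 * stats::pnorm(-abs(z)),
                         ifelse(point == 0, 1, 0)))
  if (effects == "all") {
    pct_reps <- 100 * reps / reps[, "total"]
    pct_se <- apply(pct_reps, 2, stats::sd, na.rm = TRUE)
    pct <- percent_of_total(point, point["total"])
    out$pct_of_total <- unname(pct)
    out$pct_ci_low <- unname(pct - 1.96 * pct_se)
    out$pct_ci_high <- unname(pct + 1.96 * pct_se)
    out$pct_ci_low[out$effect == "total"] <- NA_real_
    out$pct_ci_high[out$effect == "total"] <- NA_real_
  }
  attr(out, "replicates") <- reps
  attr(out, "models") <- models0
  out
}

#' Mediation analysis with multiply imputed severity
#'
#' End-to-end pipeline under missing severity data: multiply impute
#' `severe`, run the full point estimation and within-imputation bootstrap
#' on each completed dataset, and pool estimates and variances across
#' imputations by Rubin's rules. The simulation stream and the bootstrap
#' resampling seeds are shared across imputations (so between-imputation
#' variance reflects imputation uncertainty alone, and with zero missingness
#' the pooled result reproduces the complete-data pipeline exactly).
#'
#' @inheritParams bootstrap_mediation
#' @param m number of imputations (default 45).
#' @param imputation_interactions interaction mode of the imputation model.
#' @return a pooled `effect_set` with Rubin components `W`, `B_between`,
#'   `T_total` per effect and a `provenance` setting recording `m`;
#'   per-imputation estimates in attribute `per_imputation`.
#' @export
mi_analysis <- function(table, contrast, m = 45, B = 1000, n_sim = 200,
                        n_sim_boot = n_sim, seed = 1L, interactions = "full",
                        imputation_interactions = "full",
                        ordering = default_ordering(),
                        standardization = "low", effects = "all") {
  imp_seed <- derive_seed(seed, "imputation")
  sim_seed <- derive_seed(seed, "sim")
  boot_seed <- derive_seed(seed, "boot")
  imps <- impute_severity(table, m = m, seed = imp_seed,
                          interactions = imputation_interactions,
                          ordering = ordering)
  per_imp <- lapply(imps, function(ti) {
    bootstrap_mediation(ti, contrast, B = B, n_sim = n_sim,
                        n_sim_boot = n_sim_boot, seed = boot_seed,
                        interactions = interactions, ordering = ordering,
                        standardization = standardization, effects = effects,
                        sim_seed = sim_seed)
  })
  eff_names <- per_imp[[1]]$effect
  est_mat <- vapply(per_imp, function(x) x$estimate, numeric(length(eff_names)))
  var_mat <- vapply(per_imp, function(x) x$se^2, numeric(length(eff_names)))
  est_mat <- matrix(est_mat, nrow = length(eff_names))
  var_mat <- matrix(var_mat, nrow = length(eff_names))
  pooled <- lapply(seq_along(eff_names), function(i) {
    pool_rubin(est_mat[i, ], var_mat[i, ])
  })
  g <- function(f) vapply(pooled, `[[`, numeric(1), f)
  out <- new_effect_set(stats::setNames(g("estimate"), eff_names), contrast,
                        settings = list(method = "simulation+bootstrap+MI",
                                        m = m, B = B, n_sim = n_sim,
                                        n_sim_boot = n_sim_boot, seed = seed,
                                        interactions = interactions,
                                        standardization = standardization,
                                        provenance = sprintf(
                                          "Pooled results from %d multiply imputed datasets", m)))
  out$se <- g("se")
  out$ci_low <- g("ci_low")
  out$ci_high <- g("ci_high")
  out$p <- g("p")
  out$W <- g("W")
  out$B_between <- g("B")
  out$T_total <- g("T")
  if (effects == "all") {
    pct_est <- vapply(per_imp, function(x) x$pct_of_total, numeric(length(eff_names)))
    pct_var <- vapply(per_imp, function(x) {
      ((x$pct_ci_high - x$pct_ci_low) / (2 * 1.96))^2
    }, numeric(length(eff_names)))
    pct_est <- matrix(pct_est, nrow = length(eff_names))
    pct_var <- matrix(pct_var, nrow = length(eff_names))
    pp <- lapply(seq_along(eff_names), function(i) {
      if (anyNA(pct_var[i, ])) {
        list(estimate = mean(pct_est[i, ]), ci_low = NA_real_, ci_high = NA_real_)
      } else {
        pool_rubin(pct_est[i, ], pct_var[i, ])
      }
    })
    out$pct_of_total <- vapply(pp, `[[`, numeric(1), "estimate")
    out$pct_ci_low <- vapply(pp, function(x) x$ci_low, numeric(1))
    out$pct_ci_high <- vapply(pp, function(x) x$ci_high, numeric(1))
  }
  attr(out, "per_imputation") <- list(estimates = est_mat, variances = var_mat)
  out
}
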