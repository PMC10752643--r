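# Logistic model fitting and odds-ratio presentation.

#' Fit a logistic regression model by maximum likelihood
#'
#' Thin wrapper around `stats::glm.fit` (IRLS) on the design matrix built
#' from `spec`. Convergence uses a relative-deviance tolerance of 1e-8 with
#' at most 100 iterations. Complete or quasi-complete separation is flagged
#' when any coefficient exceeds 15 in absolute value on the log-odds scale.
#' Aliased (rank-deficient) columns are dropped with a warning when
#' `allow_rank_deficient` is `TRUE` — the pragmatic choice inside bootstrap
#' replicates, where resampling can empty sparse cells.
#'
#' @param table cohort table (complete for all spec variables).
#' @param spec a [model_spec()].
#' @param allow_rank_deficient drop aliased columns instead of erroring.
#' @param warm_start optional coefficient vector (same design) used as IRLS
#'   starting values to speed bootstrap refits.
#' @param quiet suppress the aliased-column warning.
#' @return an object of class `fitted_model` with elements `coefficients`
#'   (named, log-odds scale; dropped columns are absent), `vcov`, `spec`,
#'   `n`, `converged`, `iterations`, `separation`, `deviance`, `aliased`.
#' @export
fit_logistic <- function(table, spec, allow_rank_deficient = TRUE,
                         warm_start = NULL, quiet = FALSE) {
  X <- build_design(table, spec)
  y <- response_vector(table, spec)
  fit_logistic_xy(X, y, spec, allow_rank_deficient, warm_start, quiet)
}

# matrix-level fitting path shared with the fast bootstrap
fit_logistic_xy <- function(X, y, spec, allow_rank_deficient = TRUE,
                            warm_start = NULL, quiet = FALSE,
                            control = stats::glm.control(epsilon = 1e-8,
                                                         maxit = 100)) {
  if (length(unique(y)) < 2L) {
    stop("degenerate fit: response `", spec$response, "` is constant",
         call. = FALSE)
  }
  start <- NULL
  if (!is.null(warm_start)) {
    start <- rep(0, ncol(X))
    names(start) <- colnames(X)
    common <- intersect(names(warm_start), colnames(X))
    start[common] <- warm_start[common]
  }
  fit <- suppressWarnings(stats::glm.fit(
    X, y, family = stats::binomial(), start = start, control = control
  ))
  coefs <- fit$coefficients
  aliased <- names(coefs)[is.na(coefs)]
  if (length(aliased)) {
    if (!allow_rank_deficient) {
      stop("design matrix is rank deficient; aliased: ",
           paste(aliased, collapse = ", "), call. = FALSE)
    }
    if (!quiet) {
      warning("dropping aliased column(s): ", paste(aliased, collapse = ", "),
              call. = FALSE)
    }
  }
  p <- fit$rank
  piv <- fit$qr$pivot[seq_len(p)]
  Vr <- chol2inv(fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE])
  kept <- colnames(X)[piv]
  V <- matrix(NA_real_, p, p, dimnames = list(kept, kept))
  V[] <- Vr
  # reorder to design order among kept columns
  ord <- colnames(X)[colnames(X) %in% kept]
  V <- V[ord, ord, drop = FALSE]
  beta <- coefs[ord]
  structure(list(
    coefficients = beta, vcov = V, spec = spec, design_colnames = colnames(X),
    n = length(y), converged = fit$converged, iterations = fit$iter,
    separation = any(abs(beta) > 15), deviance = fit$deviance,
    aliased = aliased
  ), class = "fitted_model")
}

#' @export
print.fitted_model <- function(x, ...) {
  cat(sprintf("Logistic model for `%s`: %d coefficients, n = %d, deviance = %.2f\n",
              x$spec$response, length(x$coefficients), x$n, x$deviance))
  if (!x$converged) cat("  WARNING: IRLS did not converge\n")
  if (x$separation) cat("  WARNING: separation suspected (|coef| > 15)\n")
  if (length(x$aliased)) cat("  dropped aliased:", paste(x$aliased, collapse = ", "), "\n")
  invisible(x)
}

#' Predicted outcome probabilities
#'
#' Inverse-logit of the linear predictor for each record; strictly inside
#' (0, 1).
#'
#' @param model a `fitted_model`.
#' @param records cohort-table-like rows, complete for the model variables.
#' @return numeric probability vector.
#' @export
predict_risk <- function(model, records) {
  lp <- eval_lp(model$coefficients, as.data.frame(records))
  if (anyNA(lp)) {
    stop("missing values or unknown levels in prediction records", call. = FALSE)
  }
  stats::plogis(lp)
}

# --- model assemblers ------------------------------------------------------

match_interaction_mode <- function(interactions) {
  match.arg(interactions, c("full", "exposure_only", "none"))
}

#' Outcome model specification and fit
#'
#' Outcome regressed on SES, sex, age + age-squared, and all eleven
#' mediators. Flexibility beyond main effects is controlled by
#' `interactions`: `"full"` adds exposure-by-mediator and pairwise
#' mediator-by-mediator products (minus the anticoagulant-reperfusion
#' exclusion); `"exposure_only"` adds only exposure-by-mediator products;
#' `"none"` fits main effects only.
#'
#' @param table cohort table with complete mediator data.
#' @param ordering a [mediator_ordering()].
#' @param interactions interaction mode, see Details.
#' @param ... passed to [fit_logistic()].
#' @return a `fitted_model`.
#' @export
fit_outcome_model <- function(table, ordering = default_ordering(),
                              interactions = "full", ...) {
  fit_logistic(table, outcome_spec(ordering, interactions), ...)
}

#' @rdname fit_outcome_model
#' @export
outcome_spec <- function(ordering = default_ordering(), interactions = "full") {
  mode <- match_interaction_mode(interactions)
  meds <- ordering$mediators
  ints <- list()
  if (mode %in% c("full", "exposure_only")) {
    ints <- lapply(meds, function(m) c("ses", m))
  }
  if (mode == "full") {
    for (i in seq_along(meds)[-length(meds)]) {
      for (j in seq((i + 1), length(meds))) {
        ints <- c(ints, list(c(meds[i], meds[j])))
      }
    }
  }
  model_spec("outcome", c("ses", "sex", "age", meds), ints)
}

#' Sequential mediator models (chain-rule factorization)
#'
#' Model k regresses mediator k on SES, sex, age + age-squared, and
#' mediators 1..k-1 in the causal ordering, plus SES-by-preceding-mediator
#' interactions unless `interactions = "none"`. Jointly the fitted models
#' define the conditional mediator law P(M | A, C) by the chain rule and are
#' the engine's sampling models.
#'
#' @inheritParams fit_outcome_model
#' @return ordered list of `fitted_model`, named by mediator.
#' @export
fit_sequential_mediator_models <- function(table, ordering = default_ordering(),
                                           interactions = "full", ...) {
  specs <- sequential_specs(ordering, interactions)
  out <- lapply(specs, function(sp) fit_logistic(table, sp, ...))
  names(out) <- ordering$mediators
  out
}

#' @rdname fit_sequential_mediator_models
#' @export
sequential_specs <- function(ordering = default_ordering(), interactions = "full") {
  mode <- match_interaction_mode(interactions)
  meds <- ordering$mediators
  lapply(seq_along(meds), function(k) {
    prec <- meds[seq_len(k - 1)]
    ints <- if (mode != "none" && k > 1) lapply(prec, function(m) c("ses", m)) else list()
    model_spec(meds[k], c("ses", "sex", "age", prec), ints)
  })
}

#' Marginal mediator models (exposure-mediator associations)
#'
#' One logistic model per mediator with predictors SES, sex and age +
#' age-squared only; these feed the exposure-mediator odds-ratio rows of the
#' descriptive model table.
#'
#' @inheritParams fit_outcome_model
#' @return named list of `fitted_model`.
#' @export
fit_marginal_mediator_models <- function(table, ordering = default_ordering(), ...) {
  out <- lapply(ordering$mediators, function(m) {
    fit_logistic(table, model_spec(m, c("ses", "sex", "age")), ...)
  })
  names(out) <- ordering$mediators
  out
}

#' Odds-ratio table with Wald confidence intervals
#'
#' One row per requested contrast: OR = exp(beta), 95% CI =
#' exp(beta +/- 1.96 SE), rendered to two decimals (half-up). Because SES is
#' treatment-coded with `low` as reference, coefficients measure mid/high
#' versus low; rows requested with `negate = TRUE` flip the sign so the table
#' reads in the conventional low-versus-other direction.
#'
#' @param models named list of `fitted_model`.
#' @param rows data frame with columns `model` (name into `models`), `term`
#'   (coefficient name), `label`, and optional logical `negate`.
#' @return data frame with `label`, `or`, `ci_low`, `ci_high`, formatted
#'   columns `or_fmt`, `ci_fmt`, and a `flag` column marking separation.
#' @export
or_table <- function(models, rows) {
  if (is.null(rows$negate)) rows$negate <- FALSE
  out <- lapply(seq_len(nrow(rows)), function(i) {
    m <- models[[rows$model[i]]]
    if (is.null(m)) stop("unknown model: ", rows$model[i], call. = FALSE)
    b <- m$coefficients[rows$term[i]]
    if (is.na(b)) stop("unknown or aliased term: ", rows$term[i], call. = FALSE)
    se <- sqrt(m$vcov[rows$term[i], rows$term[i]])
    if (rows$negate[i]) b <- -b
    ci <- sort(exp(c(b - 1.96 * se, b + 1.96 * se)))
    flag <- if (m$separation) "separation" else ""
    data.frame(label = rows$label[i], or = exp(b), ci_low = ci[1],
               ci_high = ci[2], flag = flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (any(out$flag != "")) {
    warning("separation-flagged model contributes to the OR table", call. = FALSE)
  }
  out$or_fmt <- fmt_or2(out$or)
  out$ci_fmt <- sprintf("%s-%s", fmt_or2(out$ci_low), fmt_or2(out$ci_high))
  rownames(out) <- NULL
  out
}
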