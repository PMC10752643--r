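# Model specification and design-matrix construction.
#
# All logistic models (outcome, sequential mediator, marginal mediator,
# imputation) share one small term language so that fitting, Monte-Carlo
# simulation and exact enumeration evaluate literally the same linear
# predictor. Categorical variables are treatment-coded with fixed reference
# levels (SES reference = low so disparity contrasts read off coefficients
# directly; sex reference = female). Age enters centered at `AGE_CENTER`
# years before squaring; predictions are invariant to the centering, which
# exists purely for numerical conditioning.

AGE_CENTER <- 70

# expansion of a variable into design columns (reference level omitted)
expand_var <- function(var) {
  switch(var,
    ses = c("ses_mid", "ses_high"),
    sex = "sex_male",
    age = c("age_c", "age_c2"),
    aux_ambulance = c("amb_no", "amb_unknown"),
    aux_onset_to_door = paste0("onset_", c("3-4.5", "4.5-6", "6-24", ">24", "unknown")),
    var # binary variables map to themselves
  )
}

# numeric columns for one variable, given a cohort-like data frame
var_columns <- function(var, data) {
  cols <- switch(var,
    ses = list(ses_mid = as.numeric(data$ses == "mid"),
               ses_high = as.numeric(data$ses == "high")),
    sex = list(sex_male = as.numeric(data$sex == "male")),
    age = {
      ac <- data$age - AGE_CENTER
      list(age_c = ac, age_c2 = ac^2)
    },
    aux_ambulance = list(amb_no = as.numeric(data$aux_ambulance == "no"),
                         amb_unknown = as.numeric(data$aux_ambulance == "unknown")),
    aux_onset_to_door = {
      lv <- ONSET_LEVELS[-1]
      stats::setNames(lapply(lv, function(l) as.numeric(data$aux_onset_to_door == l)),
                      paste0("onset_", lv))
    },
    stats::setNames(list(as.numeric(data[[var]])), var)
  )
  cols
}

#' Specify a logistic model
#'
#' @param response response variable name.
#' @param terms main-effect variable names; `age` expands to linear and
#'   quadratic (centered) terms, categoricals to treatment-coded dummies.
#' @param interactions list of 2-element character vectors of variable names
#'   to interact (each side expands to its dummy columns).
#' @param exclusions list of unordered variable pairs never interacted;
#'   defaults to the anticoagulant-reperfusion pair, which is excluded
#'   because that cell is too sparse to support an interaction.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(response, terms, interactions = list(),
                       exclusions = list(c("anticoagulants", "reperfusion"))) {
  stopifnot(is.character(response), length(response) == 1L)
  if (response %in% terms) stop("response may not appear among terms", call. = FALSE)
  excl_key <- vapply(exclusions, function(p) paste(sort(p), collapse = "|"), character(1))
  keep <- vapply(interactions, function(p) {
    !(paste(sort(p), collapse = "|") %in% excl_key)
  }, logical(1))
  structure(list(response = response, terms = terms,
                 interactions = interactions[keep], exclusions = exclusions),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Logistic model spec: ", x$response, " ~ ",
      paste(x$terms, collapse = " + "), sep = "")
  if (length(x$interactions)) {
    cat(" +", paste(vapply(x$interactions, paste, character(1), collapse = ":"),
                    collapse = " + "))
  }
  cat("\n")
  invisible(x)
}

#' Build a design matrix for a model specification
#'
#' Deterministic column order: intercept, main-effect expansions in term
#' order, then interaction products in declaration order. Errors if any
#' specification variable contains missing values (filter or impute first).
#'
#' @param table cohort table or compatible data frame.
#' @param spec a `model_spec`.
#' @return numeric matrix with named columns.
#' @export
build_design <- function(table, spec) {
  data <- as.data.frame(table)
  for (v in unique(c(spec$terms, unlist(spec$interactions)))) {
    if (!v %in% names(data)) stop("variable not in table: ", v, call. = FALSE)
    if (anyNA(data[[v]])) {
      stop(sprintf(
        "missing values in `%s`; apply complete_case_filter() or impute_severity() first", v),
        call. = FALSE)
    }
  }
  cols <- list("(Intercept)" = rep(1, nrow(data)))
  for (v in spec$terms) cols <- c(cols, var_columns(v, data))
  for (pair in spec$interactions) {
    a_cols <- var_columns(pair[1], data)
    b_cols <- var_columns(pair[2], data)
    for (an in names(a_cols)) {
      for (bn in names(b_cols)) {
        cols[[paste0(an, ":", bn)]] <- a_cols[[an]] * b_cols[[bn]]
      }
    }
  }
  do.call(cbind, cols)
}

# response vector for a spec
response_vector <- function(table, spec) {
  y <- as.data.frame(table)[[spec$response]]
  if (is.null(y)) stop("response not in table: ", spec$response, call. = FALSE)
  if (anyNA(y)) stop("missing values in response `", spec$response, "`", call. = FALSE)
  as.numeric(y)
}
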