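# Exact enumeration of interventional disparity effects.
#
# With all mediators binary, every expectation in the estimand algebra is a
# finite sum over the 2^K mediator configurations weighted by chain-rule
# probabilities (joint scenarios) or by products of exactly marginalized
# block laws (independent-block scenarios). The outer standardization
# expectation is a weighted sum over confounder rows — observed low-SES
# records for the estimator oracle, or a quadrature grid over the
# truncated-normal age distribution for the ground truth of a synthetic
# configuration. There is no Monte-Carlo error anywhere in this module.

configs_matrix <- function(K) {
  m <- matrix(0L, 2^K, K)
  for (j in seq_len(K)) {
    m[, j] <- rep(rep(c(0L, 1L), each = 2^(j - 1)), length.out = 2^K)
  }
  m
}

# Decompose a coefficient vector at a fixed SES level into a row part
# (intercept + SES contribution, sex, age), mediator main effects (with
# SES-by-mediator interactions folded in), and mediator-pair products.
# Terms mixing age/sex with mediators are not part of any engine model.
split_model_coefs <- function(coefs, level, mediators) {
  ses_val <- c(ses_mid = as.numeric(level == "mid"),
               ses_high = as.numeric(level == "high"))
  row_terms <- c("(Intercept)" = 0, sex_male = 0, age_c = 0, age_c2 = 0)
  med_main <- stats::setNames(rep(0, length(mediators)), mediators)
  med_pairs <- list()
  for (nm in names(coefs)) {
    b <- coefs[[nm]]
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    is_ses <- parts %in% names(ses_val)
    is_med <- parts %in% mediators
    is_row <- parts %in% names(row_terms)
    if (!all(is_ses | is_med | is_row)) {
      stop("unsupported term in engine model: ", nm, call. = FALSE)
    }
    if (any(is_row) && any(is_med)) {
      stop("confounder-by-mediator terms are not supported in the engine: ",
           nm, call. = FALSE)
    }
    mult <- prod(c(1, ses_val[parts[is_ses]]))
    meds_in <- parts[is_med]
    if (length(meds_in) == 0L) {
      tgt <- if (any(is_row)) parts[is_row][1] else "(Intercept)"
      if (sum(is_row) > 1) stop("unsupported term: ", nm, call. = FALSE)
      if (all(is_ses)) tgt <- "(Intercept)"
      row_terms[tgt] <- row_terms[tgt] + b * mult
    } else if (length(meds_in) == 1L) {
      med_main[meds_in] <- med_main[meds_in] + b * mult
    } else if (length(meds_in) == 2L) {
      med_pairs[[length(med_pairs) + 1L]] <- list(a = meds_in[1], b = meds_in[2],
                                                  coef = b * mult)
    } else {
      stop("three-way mediator products are not supported: ", nm, call. = FALSE)
    }
  }
  list(row = row_terms, med_main = med_main, med_pairs = med_pairs)
}

row_offset <- function(split, rows) {
  ac <- rows$age - AGE_CENTER
  split$row[["(Intercept)"]] +
    split$row[["sex_male"]] * as.numeric(rows$sex == "male") +
    split$row[["age_c"]] * ac + split$row[["age_c2"]] * ac^2
}

cfg_contrib <- function(split, configs) {
  v <- drop(configs %*% split$med_main)
  for (p in split$med_pairs) {
    v <- v + p$coef * configs[, p$a] * configs[, p$b]
  }
  v
}

# Canonical evaluation labels for a contrast: three joint-scenario risks and
# the telescoping block path s0..s_nb (block_independent draws with blocks
# 1..k switched to the comparison level).
effect_names <- function(ordering) {
  c("total", "direct", "indirect_all",
    paste0("indirect_", names(ordering$blocks)), "indirect_dependence")
}

effects_from_evals <- function(E, ordering) {
  nb <- length(ordering$blocks)
  s <- E[paste0("s", 0:nb)]
  eff <- c(
    total = unname(E[["joint_low_out_low"]] - E[["joint_comp_out_comp"]]),
    direct = unname(E[["joint_comp_out_low"]] - E[["joint_comp_out_comp"]]),
    indirect_all = unname(E[["joint_low_out_low"]] - E[["joint_comp_out_low"]]),
    stats::setNames(-diff(unname(s)), paste0("indirect_", names(ordering$blocks))),
    indirect_dependence =
      unname((E[["joint_low_out_low"]] - s[[1]]) -
             (E[["joint_comp_out_low"]] - s[[nb + 1]]))
  )
  100 * eff
}

new_effect_set <- function(estimates, contrast, settings = list(), mc_se = NULL) {
  df <- data.frame(effect = names(estimates), estimate = unname(estimates),
                   stringsAsFactors = FALSE)
  if (!is.null(mc_se)) df$mc_se <- unname(mc_se[df$effect])
  structure(df, contrast = contrast, settings = settings,
            class = c("effect_set", "data.frame"))
}

#' @export
print.effect_set <- function(x, ...) {
  ctr <- attr(x, "contrast")
  cat(sprintf("Interventional disparity effects (low vs %s), percentage points:\n",
              ctr))
  df <- as.data.frame(x)
  df$estimate <- fmt_effect1(df$estimate)
  if (!is.null(df$ci_low)) {
    df$ci <- sprintf("(%s to %s)", fmt_effect1(df$ci_low), fmt_effect1(df$ci_high))
    df$ci_low <- df$ci_high <- NULL
  }
  print(df, row.names = FALSE)
  invisible(x)
}

check_contrast <- function(contrast) {
  match.arg(contrast, c("mid", "high"))
}

# Core exact computation: all scenario evaluations for one contrast.
enumerate_evaluations <- function(outcome_model, mediator_models, rows, weights,
                                  contrast, ordering) {
  comp <- check_contrast(contrast)
  meds <- ordering$mediators
  K <- length(meds)
  stopifnot(length(mediator_models) == K)
  configs <- configs_matrix(K)
  colnames(configs) <- meds
  nb <- length(ordering$blocks)
  block_id <- lapply(ordering$blocks, function(vars) {
    sub <- configs[, vars, drop = FALSE]
    as.integer(drop(sub %*% (2^(seq_along(vars) - 1)))) + 1L
  })

  levels2 <- c(low = "low", comp = comp)
  med_cfg <- med_off <- out_cfg <- out_off <- list()
  for (lv in names(levels2)) {
    level <- levels2[[lv]]
    splits <- lapply(mediator_models, function(m)
      split_model_coefs(m$coefficients, level, meds))
    med_cfg[[lv]] <- lapply(splits, cfg_contrib, configs = configs)
    med_off[[lv]] <- vapply(splits, row_offset, numeric(nrow(rows)), rows = rows)
    osp <- split_model_coefs(outcome_model$coefficients, level, meds)
    out_cfg[[lv]] <- cfg_contrib(osp, configs)
    out_off[[lv]] <- row_offset(osp, rows)
  }
  if (nrow(rows) == 1L) {
    med_off <- lapply(med_off, function(m) matrix(m, nrow = 1))
  }

  eval_names <- c("joint_low_out_low", "joint_comp_out_low",
                  "joint_comp_out_comp", paste0("s", 0:nb))
  E <- stats::setNames(rep(0, length(eval_names)), eval_names)
  cm <- configs == 1L
  for (i in seq_len(nrow(rows))) {
    w <- list()
    for (lv in names(levels2)) {
      wi <- rep(1, 2^K)
      for (j in seq_len(K)) {
        p <- stats::plogis(med_cfg[[lv]][[j]] + med_off[[lv]][i, j])
        wi <- wi * ifelse(cm[, j], p, 1 - p)
      }
      w[[lv]] <- wi
    }
    r_low <- stats::plogis(out_off[["low"]][i] + out_cfg[["low"]])
    r_comp <- stats::plogis(out_off[["comp"]][i] + out_cfg[["comp"]])
    wt <- weights[i]
    E[["joint_low_out_low"]] <- E[["joint_low_out_low"]] + wt * sum(w$low * r_low)
    E[["joint_comp_out_low"]] <- E[["joint_comp_out_low"]] + wt * sum(w$comp * r_low)
    E[["joint_comp_out_comp"]] <- E[["joint_comp_out_comp"]] + wt * sum(w$comp * r_comp)
    # exact block marginals of the joint law at each source level
    q <- lapply(w, function(wi) {
      lapply(seq_len(nb), function(k) {
        as.vector(rowsum(wi, block_id[[k]]))
      })
    })
    for (m in 0:nb) {
      wi <- rep(1, 2^K)
      for (k in seq_len(nb)) {
        src <- if (k <= m) "comp" else "low"
        wi <- wi * q[[src]][[k]][block_id[[k]]]
      }
      E[[paste0("s", m)]] <- E[[paste0("s", m)]] + wt * sum(wi * r_low)
    }
  }
  E
}

#' Exact interventional disparity effects from fitted models
#'
#' Enumeration counterpart of [estimate_disparity_effects()]: identical
#' estimand algebra, with every Monte-Carlo expectation replaced by an exact
#' sum over the 2^K mediator configurations. Used to verify the simulation
#' estimator (which converges to these values as the number of simulation
#' draws grows).
#'
#' @param outcome_model fitted outcome model.
#' @param mediator_models ordered list of fitted sequential mediator models.
#' @param table cohort table supplying the standardization population.
#' @param contrast `"mid"` or `"high"` (low-SES group versus that group).
#' @param ordering a [mediator_ordering()].
#' @param standardization `"low"` (confounder rows of the low-SES group,
#'   the default disparity framing) or `"cohort"` (all rows).
#' @return an `effect_set` of exact point estimates (percentage points).
#' @export
enumerate_disparity_effects <- function(outcome_model, mediator_models, table,
                                        contrast, ordering = default_ordering(),
                                        standardization = "low") {
  rows <- standardization_rows(table, standardization)
  E <- enumerate_evaluations(outcome_model, mediator_models, rows,
                             rep(1 / nrow(rows), nrow(rows)), contrast, ordering)
  new_effect_set(effects_from_evals(E, ordering), contrast,
                 settings = list(method = "enumeration",
                                 standardization = standardization,
                                 n_rows = nrow(rows)))
}

standardization_rows <- function(table, standardization = "low") {
  standardization <- match.arg(standardization, c("low", "cohort"))
  df <- as.data.frame(table)
  rows <- if (standardization == "low") df[df$ses == "low", , drop = FALSE] else df
  if (nrow(rows) == 0) stop("empty standardization population", call. = FALSE)
  rows[, c("sex", "age")]
}

# quadrature grid over (sex, age) for one SES group of a dgp_config
dgp_confounder_grid <- function(dgp, group, n_age_nodes = 64) {
  tg <- truncnorm_grid(n_age_nodes, dgp$age_mean_by_ses[[group]],
                       dgp$age_sd_by_ses[[group]], dgp$age_bounds[1],
                       dgp$age_bounds[2])
  pf <- dgp$sex_prob_by_ses[[group]]
  rows <- data.frame(
    sex = factor(rep(SEX_LEVELS, each = n_age_nodes), levels = SEX_LEVELS),
    age = rep(tg$nodes, 2)
  )
  list(rows = rows, weights = c(pf * tg$weights, (1 - pf) * tg$weights))
}

#' True interventional disparity effects of a synthetic configuration
#'
#' Ground-truth oracle: computes every estimand exactly from the structural
#' equations of a `dgp_config`, standardized over the low-SES confounder
#' distribution (sex exactly; age by `n_age_nodes`-point Gauss-Legendre
#' quadrature against the truncated-normal density). No Monte-Carlo error.
#'
#' @param dgp a `dgp_config`.
#' @param contrast `"mid"` or `"high"`.
#' @param n_age_nodes quadrature resolution for the age integral.
#' @return an `effect_set` of exact true effects (percentage points).
#' @export
true_effects <- function(dgp, contrast, n_age_nodes = 64) {
  mods <- dgp_models(dgp)
  grid <- dgp_confounder_grid(dgp, "low", n_age_nodes)
  E <- enumerate_evaluations(mods$outcome, mods$mediators, grid$rows,
                             grid$weights, contrast, dgp$ordering)
  new_effect_set(effects_from_evals(E, dgp$ordering), contrast,
                 settings = list(method = "true_enumeration",
                                 n_age_nodes = n_age_nodes))
}

#' Enumerated prevalences implied by a synthetic configuration
#'
#' For each SES group: the exact marginal prevalence of every mediator and
#' of the outcome under the structural equations (chain enumeration over
#' mediator configurations, quadrature over sex and age), plus the group
#' shares. Used to verify calibration against the published registry
#' targets without sampling.
#'
#' @param dgp a `dgp_config`.
#' @param n_age_nodes quadrature resolution.
#' @return list with `ses_probs`, `sex_prob_by_ses` and `prevalences`
#'   (matrix: variables x SES groups).
#' @export
dgp_implied_prevalences <- function(dgp, n_age_nodes = 64) {
  meds <- dgp$ordering$mediators
  K <- length(meds)
  configs <- configs_matrix(K)
  colnames(configs) <- meds
  cm <- configs == 1L
  vars <- c(meds, "outcome")
  prev <- matrix(NA_real_, length(vars), 3, dimnames = list(vars, SES_LEVELS))
  for (g in SES_LEVELS) {
    grid <- dgp_confounder_grid(dgp, g, n_age_nodes)
    splits <- lapply(dgp$mediator_eqs, split_model_coefs, level = g,
                     mediators = meds)
    cfgs <- lapply(splits, cfg_contrib, configs = configs)
    offs <- vapply(splits, row_offset, numeric(nrow(grid$rows)), rows = grid$rows)
    osp <- split_model_coefs(dgp$outcome_eq, g, meds)
    ocfg <- cfg_contrib(osp, configs)
    ooff <- row_offset(osp, grid$rows)
    acc <- stats::setNames(rep(0, length(vars)), vars)
    for (i in seq_len(nrow(grid$rows))) {
      wi <- rep(1, 2^K)
      for (j in seq_len(K)) {
        p <- stats::plogis(cfgs[[j]] + offs[i, j])
        wi <- wi * ifelse(cm[, j], p, 1 - p)
      }
      wt <- grid$weights[i]
      for (j in seq_len(K)) acc[meds[j]] <- acc[meds[j]] + wt * sum(wi * configs[, j])
      acc["outcome"] <- acc["outcome"] +
        wt * sum(wi * stats::plogis(ooff[i] + ocfg))
    }
    prev[, g] <- acc
  }
  list(ses_probs = dgp$ses_probs, sex_prob_by_ses = dgp$sex_prob_by_ses,
       prevalences = prev)
}

# exact prevalence of one variable in one SES group, enumerating only the
# chain prefix that variable depends on (fast path for calibration)
group_prevalence <- function(dgp, v, g, n_age_nodes = 64) {
  meds <- dgp$ordering$mediators
  jmax <- if (v == "outcome") length(meds) else match(v, meds)
  meds_sub <- meds[seq_len(jmax)]
  configs <- configs_matrix(jmax)
  colnames(configs) <- meds_sub
  cm <- configs == 1L
  grid <- dgp_confounder_grid(dgp, g, n_age_nodes)
  eqs <- dgp$mediator_eqs[meds_sub]
  splits <- lapply(eqs, split_model_coefs, level = g, mediators = meds_sub)
  cfgs <- lapply(splits, cfg_contrib, configs = configs)
  offs <- vapply(splits, row_offset, numeric(nrow(grid$rows)), rows = grid$rows)
  if (v == "outcome") {
    osp <- split_model_coefs(dgp$outcome_eq, g, meds_sub)
    ocfg <- cfg_contrib(osp, configs)
    ooff <- row_offset(osp, grid$rows)
  }
  out <- 0
  for (i in seq_len(nrow(grid$rows))) {
    wi <- rep(1, 2^jmax)
    for (j in seq_len(jmax)) {
      p <- stats::plogis(cfgs[[j]] + offs[i, j])
      wi <- wi * ifelse(cm[, j], p, 1 - p)
    }
    out <- out + grid$weights[i] * if (v == "outcome") {
      sum(wi * stats::plogis(ooff[i] + ocfg))
    } else {
      sum(wi * configs[, jmax])
    }
  }
  out
}

#' Calibrate the SES offsets of a synthetic configuration by enumeration
#'
#' Solves, equation by equation in causal order, the per-SES-group intercept
#' offsets so that each mediator's (and the outcome's) enumerated group
#' prevalence matches its target. Slopes are left untouched. Used once to
#' produce the frozen constants behind [default_dgp()].
#'
#' @param dgp starting `dgp_config` (its offsets are overwritten).
#' @param targets matrix of target prevalences (rows = mediators then
#'   outcome, columns = low/mid/high).
#' @param n_age_nodes quadrature resolution.
#' @return list with the calibrated `dgp` and the `offsets` matrix.
#' @export
calibrate_dgp_offsets <- function(dgp, targets, n_age_nodes = 64) {
  vars <- c(dgp$ordering$mediators, "outcome")
  stopifnot(all(vars %in% rownames(targets)))
  offsets <- matrix(NA_real_, length(vars), 3, dimnames = list(vars, SES_LEVELS))
  for (v in vars) {
    for (g in SES_LEVELS) {
      f <- function(delta) {
        d2 <- dgp
        if (v == "outcome") {
          d2$outcome_eq <- set_group_offset(d2$outcome_eq, g, delta)
        } else {
          d2$mediator_eqs[[v]] <- set_group_offset(d2$mediator_eqs[[v]], g, delta)
        }
        group_prevalence(d2, v, g, n_age_nodes) - targets[v, g]
      }
      delta <- stats::uniroot(f, c(-8, 8), tol = 1e-9)$root
      offsets[v, g] <- delta
      if (v == "outcome") {
        dgp$outcome_eq <- set_group_offset(dgp$outcome_eq, g, delta)
      } else {
        dgp$mediator_eqs[[v]] <- set_group_offset(dgp$mediator_eqs[[v]], g, delta)
      }
    }
  }
  list(dgp = dgp, offsets = offsets)
}

# rewrite an equation so that the total offset for `group` equals `value`
set_group_offset <- function(eq, group, value) {
  cur <- eq[["(Intercept)"]] +
    if (group == "mid") eq[["ses_mid"]] else if (group == "high") eq[["ses_high"]] else 0
  if (group == "low") {
    delta <- value - eq[["(Intercept)"]]
    eq[["(Intercept)"]] <- value
    # keep mid/high totals unchanged
    eq[["ses_mid"]] <- eq[["ses_mid"]] - delta
    eq[["ses_high"]] <- eq[["ses_high"]] - delta
  } else if (group == "mid") {
    eq[["ses_mid"]] <- value - eq[["(Intercept)"]]
  } else {
    eq[["ses_high"]] <- value - eq[["(Intercept)"]]
  }
  eq
}
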