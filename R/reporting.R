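# Rendering of the descriptive, regression and effect tables, and a
# deterministic end-to-end pipeline driver used by the analysis scripts.

#' Descriptive characteristics table (analogue of a registry Table 1)
#'
#' @param table a `cohort_table`.
#' @return formatted data frame from [summarize_by_ses()].
#' @export
make_table1 <- function(table) summarize_by_ses(table)

#' Fit the descriptive association models
#'
#' The three preliminary model families: exposure-outcome adjusted for
#' confounders only; exposure-mediator models (confounder-adjusted); and
#' mediator-outcome models, each adjusted for confounders and exposure,
#' plus one outcome model with all mediators jointly (main effects). These
#' are presentation models; the g-computation engine uses the flexible
#' interaction models instead.
#'
#' @param table complete `cohort_table`.
#' @param ordering a [mediator_ordering()].
#' @return named list of `fitted_model`s.
#' @export
fit_table2_models <- function(table, ordering = default_ordering()) {
  meds <- ordering$mediators
  mods <- list(
    exposure_outcome = fit_logistic(table, model_spec("outcome", c("ses", "sex", "age")))
  )
  for (m in meds) {
    mods[[paste0("marginal_", m)]] <-
      fit_logistic(table, model_spec(m, c("ses", "sex", "age")))
    mods[[paste0("mo_", m)]] <-
      fit_logistic(table, model_spec("outcome", c(m, "ses", "sex", "age")))
  }
  mods$outcome_full <- fit_outcome_model(table, ordering, interactions = "none")
  mods
}

#' Odds-ratio table of exposure, mediator and outcome associations
#' (analogue of a registry Table 2)
#'
#' @param models list from [fit_table2_models()].
#' @param ordering a [mediator_ordering()].
#' @return data frame from [or_table()].
#' @export
make_table2 <- function(models, ordering = default_ordering()) {
  meds <- ordering$mediators
  labels <- c(smoker = "smoker", diabetes = "diabetes",
              atrial_fib = "atrial fibrillation", prev_stroke = "previous stroke",
              antihypertensives = "antihypertensives", statins = "statins",
              antiplatelets = "antiplatelets", anticoagulants = "anticoagulants",
              severe = "NIHSS >5", reperfusion = "reperfusion",
              stroke_unit = "stroke unit")
  rows <- data.frame(
    model = "exposure_outcome", term = c("ses_mid", "ses_high"),
    label = c("Low vs mid SES: dead or dependent",
              "Low vs high SES: dead or dependent"),
    negate = TRUE, stringsAsFactors = FALSE)
  for (m in meds) {
    rows <- rbind(rows, data.frame(
      model = paste0("marginal_", m), term = c("ses_mid", "ses_high"),
      label = sprintf("Low vs %s SES: %s", c("mid", "high"), labels[m]),
      negate = TRUE, stringsAsFactors = FALSE))
  }
  for (m in meds) {
    rows <- rbind(rows, data.frame(
      model = paste0("mo_", m), term = m,
      label = sprintf("%s: dead or dependent", labels[m]),
      negate = FALSE, stringsAsFactors = FALSE))
  }
  for (m in meds) {
    rows <- rbind(rows, data.frame(
      model = "outcome_full", term = m,
      label = sprintf("%s: dead or dependent (adj. mediators)", labels[m]),
      negate = FALSE, stringsAsFactors = FALSE))
  }
  or_table(models, rows)
}

TABLE3_ROWS <- c(total = "Adjusted total association",
                 direct = "Direct effect",
                 indirect_all = "All mediators",
                 indirect_comorbidities = "Comorbidities",
                 indirect_severity = "NIHSS >5",
                 indirect_reperfusion = "Reperfusion",
                 indirect_stroke_unit = "Stroke unit",
                 indirect_dependence = "Dependence between mediators")

#' Effect decomposition table (analogue of a registry Table 3)
#'
#' Fixed row order (adjusted total association; direct effect; indirect
#' effects through all mediators, then each block; dependence between
#' mediators), one-decimal effects with `(low to high)` confidence
#' intervals, p-values, and percent of the adjusted total association.
#' Signs of effects that round to zero are preserved (`-0.0`).
#'
#' @param effects an `effect_set` (with or without bootstrap columns).
#' @return data frame of formatted cells; raw values kept as numeric
#'   columns prefixed `raw_`.
#' @export
make_table3 <- function(effects) {
  df <- as.data.frame(effects)
  miss <- setdiff(names(TABLE3_ROWS), df$effect)
  out <- data.frame(effect = names(TABLE3_ROWS),
                    label = unname(TABLE3_ROWS), stringsAsFactors = FALSE)
  out <- merge(out, df, by = "effect", all.x = TRUE, sort = FALSE)
  out <- out[match(names(TABLE3_ROWS), out$effect), , drop = FALSE]
  fmt_ci <- function(e, lo, hi) {
    ifelse(is.na(lo), fmt_effect1(e),
           sprintf("%s (%s to %s)", fmt_effect1(e), fmt_effect1(lo),
                   fmt_effect1(hi)))
  }
  has <- function(nm) !is.null(out[[nm]])
  res <- data.frame(label = out$label, stringsAsFactors = FALSE)
  res$estimate <- fmt_ci(out$estimate,
                         if (has("ci_low")) out$ci_low else NA,
                         if (has("ci_high")) out$ci_high else NA)
  if (has("p")) res$p <- fmt_p(out$p)
  if (has("pct_of_total")) {
    res$pct_of_total <- ifelse(
      out$effect == "total", "",
      fmt_ci(out$pct_of_total,
             if (has("pct_ci_low")) out$pct_ci_low else NA,
             if (has("pct_ci_high")) out$pct_ci_high else NA))
  }
  res$raw_estimate <- out$estimate
  if (has("se")) res$raw_se <- out$se
  if (length(miss)) {
    warning("missing effect component(s): ", paste(miss, collapse = ", "),
            call. = FALSE)
    res$estimate[is.na(out$estimate)] <- "(not estimated)"
  }
  rownames(res) <- NULL
  res
}

#' Serialize an effect set to JSON
#'
#' Records the estimates plus the estimator settings (simulation draws,
#' seeds, coupling, standardization) for reproducibility.
#'
#' @param effects an `effect_set`.
#' @param path optional output path; if `NULL` the JSON string is returned.
#' @return path or JSON string.
#' @export
effect_set_json <- function(effects, path = NULL) {
  x <- list(contrast = attr(effects, "contrast"),
            settings = attr(effects, "settings"),
            effects = as.data.frame(effects))
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Stages: load or generate the cohort; validate; complete-case filter;
#' multiply impute severity if missing (otherwise a single complete-data
#' analysis); fit descriptive models; estimate the disparity decomposition
#' with bootstrap (and Rubin pooling under imputation); render the
#' descriptive, odds-ratio and effect tables. Every stage is logged with
#' row counts and seeds; outputs are deterministic given the configuration.
#'
#' @param config list with either `table` (a `cohort_table`) or `synthetic`
#'   (list with `n`, optional `dgp`, optional `missing_target`); and
#'   optional `contrasts` (default `c("mid", "high")`), `n_sim`, `B`, `m`,
#'   `interactions`, `seed`, `output_dir`.
#' @return list with `table1`, `table2`, `effects` (per contrast),
#'   `table3` (per contrast), `log`.
#' @export
run_mediation_pipeline <- function(config) {
  cfg <- utils::modifyList(list(contrasts = c("mid", "high"), n_sim = 200,
                                B = 1000, m = 45, interactions = "full",
                                seed = 1L, output_dir = NULL), config)
  if (is.null(cfg$table) == is.null(cfg$synthetic)) {
    stop("exactly one of `table` or `synthetic` must be given", call. = FALSE)
  }
  log_lines <- character(0)
  logf <- function(stage, ...) {
    line <- sprintf("[%s] %s", stage, sprintf(...))
    log_lines <<- c(log_lines, line)
    message(line)
  }
  if (!is.null(cfg$synthetic)) {
    dgp <- cfg$synthetic$dgp %||% default_dgp()
    gen_seed <- derive_seed(cfg$seed, "generation")
    tab <- generate_cohort(dgp, cfg$synthetic$n, gen_seed)
    logf("generate", "n = %d, seed = %d", nrow(tab), gen_seed)
    mt <- cfg$synthetic$missing_target %||% 0
    if (mt > 0) {
      miss_seed <- derive_seed(cfg$seed, "missingness")
      tab <- inject_missingness(tab, missingness_config(target = mt), miss_seed)
      logf("missingness", "target = %.3f, realized = %.3f, seed = %d", mt,
           mean(is.na(tab$severe)), miss_seed)
    }
  } else {
    tab <- cfg$table
    logf("load", "n = %d (%s)", nrow(tab), attr(tab, "provenance"))
  }
  tab <- complete_case_filter(tab)
  rep <- attr(tab, "filter_report")
  logf("complete_case", "kept %d of %d records", rep$n_out, rep$n_in)

  t1 <- make_table1(tab)
  has_missing <- anyNA(tab$severe)
  t2_tab <- if (has_missing) {
    imp1 <- impute_severity(tab, m = 1, seed = derive_seed(cfg$seed, "imputation_t2"),
                            interactions = "none")[[1]]
    logf("table2", "descriptive models on a single imputed dataset")
    imp1
  } else tab
  t2 <- make_table2(fit_table2_models(t2_tab))

  effects <- list()
  t3 <- list()
  for (ctr in cfg$contrasts) {
    eff <- if (has_missing) {
      logf("effects", "contrast low vs %s: MI m = %d, B = %d, n_sim = %d",
           ctr, cfg$m, cfg$B, cfg$n_sim)
      mi_analysis(tab, ctr, m = cfg$m, B = cfg$B, n_sim = cfg$n_sim,
                  seed = cfg$seed, interactions = cfg$interactions)
    } else {
      logf("effects", "contrast low vs %s: B = %d, n_sim = %d", ctr, cfg$B,
           cfg$n_sim)
      bootstrap_mediation(tab, ctr, B = cfg$B, n_sim = cfg$n_sim,
                          seed = derive_seed(cfg$seed, "boot"),
                          sim_seed = derive_seed(cfg$seed, "sim"),
                          interactions = cfg$interactions)
    }
    effects[[ctr]] <- eff
    t3[[ctr]] <- make_table3(eff)
  }

  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(t1, file.path(cfg$output_dir, "table1.csv"), row.names = FALSE)
    utils::write.csv(t2, file.path(cfg$output_dir, "table2.csv"), row.names = FALSE)
    for (ctr in names(t3)) {
      utils::write.csv(t3[[ctr]],
                       file.path(cfg$output_dir, sprintf("table3_low_vs_%s.csv", ctr)),
                       row.names = FALSE)
      effect_set_json(effects[[ctr]],
                      file.path(cfg$output_dir, sprintf("results_low_vs_%s.json", ctr)))
    }
    writeLines(log_lines, file.path(cfg$output_dir, "run.log"))
    logf("write", "outputs under %s", cfg$output_dir)
  }
  list(table1 = t1, table2 = t2, effects = effects, table3 = t3, log = log_lines)
}
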