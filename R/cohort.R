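# Registry-style cohort container: variable coding, validation, CSV I/O.
#
# The analysis dataset holds a 3-level socioeconomic exposure, two baseline
# confounders (sex, age), eleven binary mediators in four causally ordered
# blocks, a binary outcome (dead or ADL dependent at 3 months), and three
# auxiliary variables used only by the imputation model for the severity
# mediator (NIHSS > 5), which is the single variable allowed to be missing
# in analysis data.

SES_LEVELS <- c("low", "mid", "high")
SEX_LEVELS <- c("female", "male")
AMBULANCE_LEVELS <- c("yes", "no", "unknown")
ONSET_LEVELS <- c("<3", "3-4.5", "4.5-6", "6-24", ">24", "unknown")

COMORBIDITY_VARS <- c("smoker", "diabetes", "atrial_fib", "prev_stroke",
                      "antihypertensives", "statins", "antiplatelets",
                      "anticoagulants")
MEDIATOR_VARS <- c(COMORBIDITY_VARS, "severe", "reperfusion", "stroke_unit")
AUX_VARS <- c("aux_rls_gt1", "aux_ambulance", "aux_onset_to_door")

COHORT_COLUMNS <- c("ses", "sex", "age", MEDIATOR_VARS, "outcome", AUX_VARS)

BINARY_VARS <- c(MEDIATOR_VARS, "outcome", "aux_rls_gt1")

# income tertile cutoffs (SEK, year before stroke) shipped as codebook
# metadata; tertile construction itself is out of analytic scope
INCOME_TERTILE_CUTOFFS_SEK <- list(
  "2015" = c(lowest_below = 155033, highest_above = 220300),
  "2016" = c(lowest_below = 157300, highest_above = 229700)
)

#' Causal ordering of the mediators
#'
#' The eleven binary mediators are grouped into four blocks whose order
#' reflects the hypothesized causal structure: pre-stroke comorbidities and
#' medications precede stroke severity, which precedes the acute-care
#' variables (reperfusion therapy, then stroke-unit care). Sequential
#' mediator models and the telescoping block decomposition both follow this
#' order.
#'
#' @param blocks named list of character vectors, each naming the mediator
#'   variables of one block, in causal order.
#' @return an object of class `mediator_ordering`.
#' @export
mediator_ordering <- function(blocks = list(
  comorbidities = COMORBIDITY_VARS,
  severity = "severe",
  reperfusion = "reperfusion",
  stroke_unit = "stroke_unit"
)) {
  vars <- unlist(blocks, use.names = FALSE)
  if (anyDuplicated(vars)) {
    stop("every mediator must appear in exactly one block", call. = FALSE)
  }
  if (is.null(names(blocks)) || any(names(blocks) == "")) {
    stop("blocks must be named", call. = FALSE)
  }
  structure(list(blocks = blocks, mediators = vars),
            class = "mediator_ordering")
}

#' Default four-block mediator ordering
#' @return a `mediator_ordering`.
#' @export
default_ordering <- function() mediator_ordering()

#' @export
print.mediator_ordering <- function(x, ...) {
  cat("Mediator ordering (", length(x$mediators), " mediators, ",
      length(x$blocks), " blocks):\n", sep = "")
  for (b in names(x$blocks)) {
    cat("  ", b, ": ", paste(x$blocks[[b]], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

canon_level <- function(x, levels, var, rows_are = seq_along(x)) {
  xc <- tolower(trimws(as.character(x)))
  xc[xc == ""] <- NA_character_
  bad <- !is.na(xc) & !(xc %in% levels)
  if (any(bad)) {
    stop(sprintf("illegal level(s) for `%s` in rows %s: %s", var,
                 paste(utils::head(rows_are[bad], 10), collapse = ", "),
                 paste(unique(xc[bad]), collapse = ", ")),
         call. = FALSE)
  }
  factor(xc, levels = levels)
}

canon_binary <- function(x, var, rows_are = seq_along(x)) {
  if (is.logical(x)) x <- as.integer(x)
  xc <- trimws(as.character(x))
  xc[xc %in% c("", "NA")] <- NA_character_
  map <- c("0" = 0L, "1" = 1L, "true" = 1L, "false" = 0L, "yes" = 1L, "no" = 0L)
  v <- map[tolower(xc)]
  bad <- !is.na(xc) & is.na(v)
  if (any(bad)) {
    stop(sprintf("illegal value(s) for binary `%s` in rows %s: %s", var,
                 paste(utils::head(rows_are[bad], 10), collapse = ", "),
                 paste(unique(xc[bad]), collapse = ", ")),
         call. = FALSE)
  }
  as.integer(v)
}

#' Construct a validated cohort table
#'
#' Canonicalizes levels (case/whitespace), coerces binaries to 0/1 integers,
#' and validates the record invariants: in strict mode only the severity
#' mediator `severe` may be missing; `age` must be positive and finite;
#' categorical fields take only their declared levels. `"unknown"` is a legal
#' level (not missing) for the two categorical auxiliaries.
#'
#' @param df data frame with the canonical codebook columns (any order).
#' @param provenance free-text label recording where the records came from.
#' @param codebook codebook version tag.
#' @param strict if `TRUE` (analysis data), missing values outside `severe`
#'   are an error; if `FALSE` (pre-filter raw data), they are allowed and can
#'   be removed later with [complete_case_filter()].
#' @return a `cohort_table` (a validated data frame).
#' @export
cohort_table <- function(df, provenance = "unspecified", codebook = "1.0",
                         strict = TRUE) {
  missing_cols <- setdiff(COHORT_COLUMNS, names(df))
  extra_cols <- setdiff(names(df), COHORT_COLUMNS)
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (length(extra_cols)) {
    stop("unknown column(s): ", paste(extra_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- df[, COHORT_COLUMNS, drop = FALSE]
  n <- nrow(df)
  rows <- seq_len(n)

  df$ses <- canon_level(df$ses, SES_LEVELS, "ses", rows)
  df$sex <- canon_level(df$sex, SEX_LEVELS, "sex", rows)
  df$aux_ambulance <- canon_level(df$aux_ambulance, AMBULANCE_LEVELS,
                                  "aux_ambulance", rows)
  df$aux_onset_to_door <- canon_level(df$aux_onset_to_door, ONSET_LEVELS,
                                      "aux_onset_to_door", rows)
  df$age <- suppressWarnings(as.numeric(df$age))
  for (v in BINARY_VARS) df[[v]] <- canon_binary(df[[v]], v, rows)

  if (n > 0) {
    bad_age <- !is.na(df$age) & (!is.finite(df$age) | df$age <= 0)
    if (any(bad_age)) {
      stop("age must be finite and > 0; offending rows: ",
           paste(utils::head(rows[bad_age], 10), collapse = ", "),
           call. = FALSE)
    }
    if (strict) {
      for (v in setdiff(COHORT_COLUMNS, "severe")) {
        if (anyNA(df[[v]])) {
          stop(sprintf(
            "missing values in `%s` (rows %s); only `severe` may be missing in analysis data - run complete_case_filter() or use strict = FALSE",
            v, paste(utils::head(rows[is.na(df[[v]])], 10), collapse = ", ")),
            call. = FALSE)
        }
      }
    }
  }
  rownames(df) <- NULL
  structure(df, provenance = provenance, codebook = codebook,
            class = c("cohort_table", "data.frame"))
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("Cohort table: %d records (provenance: %s, codebook %s)\n",
              nrow(x), attr(x, "provenance"), attr(x, "codebook")))
  if (nrow(x)) {
    cat(sprintf("  SES: %s\n",
                paste(sprintf("%s %d", levels(x$ses), table(x$ses)),
                      collapse = ", ")))
    cat(sprintf("  severity missing: %d (%.1f%%)\n", sum(is.na(x$severe)),
                100 * mean(is.na(x$severe))))
  }
  invisible(x)
}

#' Read a cohort CSV
#'
#' Reads a comma-separated UTF-8 file with the canonical codebook header
#' (any column order), canonicalizes levels, and validates. An empty field in
#' `severe` denotes a missing severity measurement.
#'
#' @param path file path.
#' @param strict passed to [cohort_table()].
#' @param provenance provenance label; defaults to the file name.
#' @return a `cohort_table`.
#' @export
read_cohort <- function(path, strict = TRUE, provenance = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        fileEncoding = "UTF-8")
  cohort_table(df, provenance = provenance, strict = strict)
}

#' Write a cohort CSV
#'
#' Writes canonical column order, comma separation, UTF-8; missing `severe`
#' becomes an empty field. `age` is written with 17 significant digits so
#' that `read_cohort(write_cohort(t))` reproduces `t` exactly.
#'
#' @param table a `cohort_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path) {
  stopifnot(inherits(table, "cohort_table"))
  out <- as.data.frame(table)[, COHORT_COLUMNS, drop = FALSE]
  out$age <- vapply(out$age, function(a) sprintf("%.17g", a), character(1))
  for (v in names(out)) out[[v]] <- as.character(out[[v]])
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "",
                     fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("could not write ", path, ": ", conditionMessage(ok),
                        call. = FALSE)
  invisible(path)
}

#' Compose the socioeconomic exposure from education and income
#'
#' The three-level composite: `low` requires primary-school education and
#' income in the lowest tertile; `high` requires university education and
#' income in the highest tertile; everyone in between is `mid`.
#'
#' @param education factor/character in `{primary, secondary, university}`.
#' @param income_tertile integer/character in `{1, 2, 3}`.
#' @return factor with levels low/mid/high.
#' @export
compose_ses <- function(education, income_tertile) {
  edu <- tolower(trimws(as.character(education)))
  bad <- !(edu %in% c("primary", "secondary", "university"))
  if (any(bad)) stop("invalid education level: ",
                     paste(unique(edu[bad]), collapse = ", "), call. = FALSE)
  tert <- trimws(as.character(income_tertile))
  if (any(!(tert %in% c("1", "2", "3")))) {
    stop("income_tertile must be 1, 2 or 3", call. = FALSE)
  }
  out <- rep("mid", length(edu))
  out[edu == "primary" & tert == "1"] <- "low"
  out[edu == "university" & tert == "3"] <- "high"
  factor(out, levels = SES_LEVELS)
}

#' Patient characteristics by SES group
#'
#' Per SES level: record count and column share, each binary variable as
#' `"count (pct)"` with the percentage computed within the SES group over
#' non-missing records, age as `"mean, sd"`, and an overall per-variable
#' missing percentage. Percentages use one decimal, rounded half-up.
#'
#' @param table a `cohort_table` (strict or permissive).
#' @return data frame of formatted cells, one row per characteristic, with a
#'   `counts` attribute holding the raw numerators/denominators.
#' @export
summarize_by_ses <- function(table) {
  stopifnot(inherits(table, "cohort_table"))
  vars <- c("outcome", MEDIATOR_VARS, "female")
  labels <- c(outcome = "Dead or ADL dependent at 3 mo", smoker = "Smoker",
              diabetes = "Diabetes", atrial_fib = "Atrial fibrillation",
              prev_stroke = "Previous stroke",
              antihypertensives = "Antihypertensives", statins = "Statins",
              antiplatelets = "Antiplatelets", anticoagulants = "Anticoagulants",
              severe = "NIHSS >5", reperfusion = "Reperfusion therapy",
              stroke_unit = "Stroke unit", female = "Female sex")
  n_total <- nrow(table)
  out <- data.frame(characteristic = c("Total number", labels[vars],
                                       "Age, y, mean (SD)"),
                    stringsAsFactors = FALSE)
  counts <- list()
  for (g in SES_LEVELS) {
    sub <- table[!is.na(table$ses) & table$ses == g, , drop = FALSE]
    n_g <- nrow(sub)
    cells <- fmt_count_pct(n_g, n_total)
    cnt <- c(total = n_g)
    for (v in vars) {
      x <- if (v == "female") as.integer(sub$sex == "female") else sub[[v]]
      denom <- sum(!is.na(x))
      num <- sum(x, na.rm = TRUE)
      cells <- c(cells, fmt_count_pct(num, denom))
      cnt[v] <- num
      cnt[paste0(v, "_denom")] <- denom
    }
    age_cell <- if (n_g > 0) {
      sprintf("%s, %s",
              formatC(round_half_up(mean(sub$age), 1), format = "f", digits = 1),
              formatC(round_half_up(stats::sd(sub$age), 1), format = "f", digits = 1))
    } else ""
    out[[g]] <- c(cells, age_cell)
    counts[[g]] <- cnt
  }
  miss <- vapply(c("ses", vars, "age"), function(v) {
    x <- switch(v, female = table$sex, ses = table$ses, table[[v]])
    if (n_total > 0) round_half_up(100 * mean(is.na(x)), 1) else 0
  }, numeric(1))
  out$missing_pct <- formatC(miss, format = "f", digits = 1)
  attr(out, "counts") <- counts
  out
}
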