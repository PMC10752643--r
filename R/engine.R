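# Monte-Carlo g-computation of interventional disparity effects.
#
# Risks are averaged predicted outcome probabilities over mediator vectors
# simulated from the fitted sequential mediator models, standardized over a
# confounder population. One uniform stream is shared by every scenario
# (common random numbers), so that (i) the decomposition identities
# direct + indirect_all = total and sum(block indirects) + dependence =
# indirect_all hold exactly by construction, and (ii) scenarios with
# identical mediator laws produce identical draws, making null indirect
# effects exactly zero.
#
# Scenario vocabulary: a "joint" draw runs one ancestral pass through the
# whole mediator chain at a single source SES level, preserving the fitted
# between-mediator dependence. A "block_independent" draw runs one ancestral
# pass per block at that block's source level and keeps only that block's
# values, integrating the preceding blocks out by simulation; combined
# across passes the blocks are mutually independent with correct block
# marginals. Out-of-block mediators use per-pass auxiliary uniform streams
# (shared across scenarios) so cross-block dependence is genuinely broken
# while common random numbers are retained for the retained values.

# per-level preparation of one model for fast repeated evaluation
prep_model <- function(model, level, rows_stack, mediators) {
  sp <- split_model_coefs(model$coefficients, level, mediators)
  list(offset = row_offset(sp, rows_stack), med_main = sp$med_main,
       med_pairs = sp$med_pairs)
}

prep_lp <- function(prep, M) {
  lp <- prep$offset + drop(M %*% prep$med_main)
  for (p in prep$med_pairs) lp <- lp + p$coef * M[, p$a] * M[, p$b]
  lp
}

chain_draw_stack <- function(preps, U, K, upto = K) {
  M <- matrix(0, nrow(U), K)
  colnames(M) <- names(preps)
  for (j in seq_len(upto)) {
    lp <- prep_lp(preps[[j]], M)
    M[, j] <- as.numeric(U[, j] < stats::plogis(lp))
  }
  M
}

# All scenario evaluations for one contrast, per simulation repetition.
# Returns an n_sim x n_evaluation matrix of standardized risks.
simulate_evaluations <- function(outcome_model, mediator_models, rows, contrast,
                                 n_sim, seed, ordering, which = "all") {
  comp <- check_contrast(contrast)
  which <- match.arg(which, c("all", "total"))
  meds <- ordering$mediators
  K <- length(meds)
  stopifnot(length(mediator_models) == K, n_sim >= 1)
  nb <- length(ordering$blocks)
  nr <- nrow(rows)
  N <- nr * n_sim
  rep_id <- rep(seq_len(n_sim), each = nr)
  # plain list, not a data frame: avoids rowname bookkeeping on the stack
  rows_stack <- list(sex = rep(rows$sex, times = n_sim),
                     age = rep(rows$age, times = n_sim))

  levels2 <- c(low = "low", comp = comp)
  med_preps <- out_preps <- list()
  for (lv in names(levels2)) {
    med_preps[[lv]] <- stats::setNames(
      lapply(mediator_models, prep_model, level = levels2[[lv]],
             rows_stack = rows_stack, mediators = meds), meds)
    out_preps[[lv]] <- prep_model(outcome_model, levels2[[lv]], rows_stack, meds)
  }

  block_end <- cumsum(lengths(ordering$blocks))
  risk_rep <- function(out_prep, M) {
    as.vector(rowsum(stats::plogis(prep_lp(out_prep, M)), rep_id)) / nr
  }

  with_seed(seed, {
    U <- matrix(stats::runif(N * K), N, K)
    joint <- lapply(med_preps, chain_draw_stack, U = U, K = K)
    E <- list(
      joint_low_out_low = risk_rep(out_preps$low, joint$low),
      joint_comp_out_low = risk_rep(out_preps$low, joint$comp),
      joint_comp_out_comp = risk_rep(out_preps$comp, joint$comp)
    )
    if (which == "all") {
      # one auxiliary stream per block pass, shared across scenarios
      V <- lapply(seq_len(nb), function(k) matrix(stats::runif(N * K), N, K))
      pass <- list()
      for (k in seq_len(nb)) {
        in_block <- meds %in% ordering$blocks[[k]]
        Umix <- V[[k]]
        Umix[, in_block] <- U[, in_block]
        pass[[k]] <- lapply(med_preps, chain_draw_stack, U = Umix, K = K,
                            upto = block_end[k])
      }
      for (m in 0:nb) {
        M <- matrix(0, N, K)
        colnames(M) <- meds
        for (k in seq_len(nb)) {
          src <- if (k <= m) "comp" else "low"
          vars <- ordering$blocks[[k]]
          M[, vars] <- pass[[k]][[src]][, vars]
        }
        E[[paste0("s", m)]] <- risk_rep(out_preps$low, M)
      }
    }
    do.call(cbind, E)
  })
}

#' Define a simulation scenario
#'
#' A scenario fixes the SES level plugged into the outcome model, the SES
#' level whose fitted mediator law drives each block's draw, and whether the
#' blocks are drawn jointly (one ancestral pass, all sources equal) or
#' independently (one pass per block, combined across passes).
#'
#' @param outcome_exposure SES level for the outcome model.
#' @param block_sources named character vector, one SES level per block.
#' @param coupling `"joint"` or `"block_independent"`.
#' @param ordering a [mediator_ordering()].
#' @return an object of class `scenario`.
#' @export
scenario <- function(outcome_exposure, block_sources,
                     coupling = c("joint", "block_independent"),
                     ordering = default_ordering()) {
  coupling <- match.arg(coupling)
  outcome_exposure <- match.arg(outcome_exposure, SES_LEVELS)
  if (length(block_sources) == 1L) {
    block_sources <- stats::setNames(rep(block_sources, length(ordering$blocks)),
                                     names(ordering$blocks))
  }
  stopifnot(all(names(ordering$blocks) %in% names(block_sources)),
            all(block_sources %in% SES_LEVELS))
  block_sources <- block_sources[names(ordering$blocks)]
  if (coupling == "joint" && length(unique(block_sources)) > 1L) {
    stop("joint coupling requires all block sources to be equal", call. = FALSE)
  }
  structure(list(outcome_exposure = outcome_exposure,
                 block_sources = block_sources, coupling = coupling,
                 ordering = ordering),
            class = "scenario")
}

#' Draw mediator vectors under a scenario from pre-drawn uniforms
#'
#' Ancestral sampling through the fitted chain: each mediator value is the
#' indicator `uniform < predicted probability`. For block-independent
#' coupling, per-block auxiliary uniforms drive the integrated-out preceding
#' mediators of each pass.
#'
#' @param mediator_models ordered list of fitted sequential mediator models.
#' @param rows confounder rows (`sex`, `age`).
#' @param scn a [scenario()].
#' @param uniforms numeric matrix (rows x mediators) of uniforms.
#' @param aux_uniforms list (one matrix per block) of auxiliary uniforms;
#'   required for block-independent coupling.
#' @return integer 0/1 matrix (rows x mediators).
#' @export
draw_mediators <- function(mediator_models, rows, scn, uniforms,
                           aux_uniforms = NULL) {
  stopifnot(inherits(scn, "scenario"))
  ordering <- scn$ordering
  meds <- ordering$mediators
  K <- length(meds)
  if (!is.matrix(uniforms) || nrow(uniforms) != nrow(rows) || ncol(uniforms) != K) {
    stop("uniforms must be a rows x mediators matrix", call. = FALSE)
  }
  preps_at <- function(level) stats::setNames(
    lapply(mediator_models, prep_model, level = level, rows_stack = rows,
           mediators = meds), meds)
  if (scn$coupling == "joint") {
    M <- chain_draw_stack(preps_at(scn$block_sources[[1]]), uniforms, K)
  } else {
    if (is.null(aux_uniforms) || length(aux_uniforms) != length(ordering$blocks)) {
      stop("block-independent coupling needs one auxiliary uniform matrix per block",
           call. = FALSE)
    }
    block_end <- cumsum(lengths(ordering$blocks))
    M <- matrix(0, nrow(rows), K)
    colnames(M) <- meds
    for (k in seq_along(ordering$blocks)) {
      in_block <- meds %in% ordering$blocks[[k]]
      Umix <- aux_uniforms[[k]]
      if (!is.matrix(Umix) || any(dim(Umix) != dim(uniforms))) {
        stop("auxiliary uniforms must match the dimensions of `uniforms`",
             call. = FALSE)
      }
      Umix[, in_block] <- uniforms[, in_block]
      pass <- chain_draw_stack(preps_at(scn$block_sources[[k]]), Umix, K,
                               upto = block_end[k])
      vars <- ordering$blocks[[k]]
      M[, vars] <- pass[, vars]
    }
  }
  storage.mode(M) <- "integer"
  M
}

#' Standardized risk under a scenario
#'
#' For each of `n_sim` repetitions: draw one mediator vector per
#' standardization row from the scenario's mediator law, evaluate the
#' outcome model at the scenario's outcome exposure, and average over rows;
#' the returned risk is the grand mean over repetitions. Deterministic given
#' `seed`, with the uniform stream laid out so that different scenarios
#' evaluated under the same seed share their random numbers.
#'
#' @param outcome_model fitted outcome model.
#' @param mediator_models ordered list of fitted sequential mediator models.
#' @param table cohort table supplying the standardization population.
#' @param scn a [scenario()].
#' @param n_sim number of simulation repetitions (default 200).
#' @param seed integer seed.
#' @param standardization `"low"` or `"cohort"`.
#' @return mean risk (probability), with per-repetition means as attribute
#'   `"reps"`.
#' @export
scenario_risk <- function(outcome_model, mediator_models, table, scn,
                          n_sim = 200, seed = 1L, standardization = "low") {
  stopifnot(inherits(scn, "scenario"), n_sim >= 1)
  ordering <- scn$ordering
  rows <- standardization_rows(table, standardization)
  meds <- ordering$mediators
  K <- length(meds)
  nr <- nrow(rows)
  N <- nr * n_sim
  rep_id <- rep(seq_len(n_sim), each = nr)
  rows_stack <- list(sex = rep(rows$sex, times = n_sim),
                     age = rep(rows$age, times = n_sim))
  out_prep <- prep_model(outcome_model, scn$outcome_exposure, rows_stack, meds)
  reps <- with_seed(seed, {
    U <- matrix(stats::runif(N * K), N, K)
    if (scn$coupling == "joint") {
      preps <- stats::setNames(
        lapply(mediator_models, prep_model, level = scn$block_sources[[1]],
               rows_stack = rows_stack, mediators = meds), meds)
      M <- chain_draw_stack(preps, U, K)
    } else {
      nb <- length(ordering$blocks)
      V <- lapply(seq_len(nb), function(k) matrix(stats::runif(N * K), N, K))
      block_end <- cumsum(lengths(ordering$blocks))
      M <- matrix(0, N, K)
      colnames(M) <- meds
      for (k in seq_len(nb)) {
        in_block <- meds %in% ordering$blocks[[k]]
        Umix <- V[[k]]
        Umix[, in_block] <- U[, in_block]
        preps <- stats::setNames(
          lapply(mediator_models, prep_model, level = scn$block_sources[[k]],
                 rows_stack = rows_stack, mediators = meds), meds)
        pass <- chain_draw_stack(preps, Umix, K, upto = block_end[k])
        vars <- ordering$blocks[[k]]
        M[, vars] <- pass[, vars]
      }
    }
    as.vector(rowsum(stats::plogis(prep_lp(out_prep, M)), rep_id)) / nr
  })
  structure(mean(reps), reps = reps)
}

#' Monte-Carlo estimate of the full disparity decomposition
#'
#' Point estimates of the adjusted total association and the interventional
#' disparity direct, joint indirect, block-specific indirect and
#' mediator-dependence effects, in percentage points, standardized over the
#' low-SES confounder rows by default. With `R(a, D)` the standardized risk
#' under outcome exposure `a` and mediator law `D` (all evaluated on one
#' shared uniform stream):
#' total = R(low, joint at low) - R(comp, joint at comp);
#' indirect (all) = R(low, joint at low) - R(low, joint at comp);
#' direct = R(low, joint at comp) - R(comp, joint at comp);
#' block indirects telescope through block-independent scenarios that switch
#' blocks to the comparison level one causal block at a time, and the
#' dependence effect is the difference between the joint and
#' block-independent laws at the two levels. The identities
#' direct + indirect_all = total and
#' sum(block indirects) + dependence = indirect_all hold exactly.
#'
#' @inheritParams scenario_risk
#' @param contrast `"mid"` or `"high"`.
#' @param ordering a [mediator_ordering()].
#' @return an `effect_set` with point estimates and Monte-Carlo standard
#'   errors (`mc_se`; sampling noise of the simulation step only, not
#'   statistical uncertainty — see [bootstrap_mediation()]).
#' @export
estimate_disparity_effects <- function(outcome_model, mediator_models, table,
                                       contrast, n_sim = 200, seed = 1L,
                                       ordering = default_ordering(),
                                       standardization = "low") {
  rows <- standardization_rows(table, standardization)
  R <- simulate_evaluations(outcome_model, mediator_models, rows, contrast,
                            n_sim, seed, ordering)
  per_rep <- t(apply(R, 1, effects_from_evals, ordering = ordering))
  est <- colMeans(per_rep)
  mc_se <- apply(per_rep, 2, stats::sd) / sqrt(n_sim)
  new_effect_set(est, contrast,
                 settings = list(method = "simulation", n_sim = n_sim,
                                 seed = seed, standardization = standardization,
                                 n_rows = nrow(rows)),
                 mc_se = mc_se)
}

#' Adjusted total association between SES and the outcome
#'
#' Absolute difference (percentage points) between the standardized risk of
#' the low-SES group and that of the comparison group, each with mediators
#' drawn jointly at the group's own level, adjusted for sex and age by
#' standardization over the low-SES confounder rows.
#'
#' @inheritParams estimate_disparity_effects
#' @return one-row `effect_set`.
#' @export
adjusted_total_association <- function(outcome_model, mediator_models, table,
                                       contrast, n_sim = 200, seed = 1L,
                                       ordering = default_ordering(),
                                       standardization = "low") {
  rows <- standardization_rows(table, standardization)
  R <- simulate_evaluations(outcome_model, mediator_models, rows, contrast,
                            n_sim, seed, ordering, which = "total")
  per_rep <- 100 * (R[, "joint_low_out_low"] - R[, "joint_comp_out_comp"])
  new_effect_set(c(total = mean(per_rep)), contrast,
                 settings = list(method = "simulation", n_sim = n_sim,
                                 seed = seed, standardization = standardization),
                 mc_se = c(total = stats::sd(per_rep) / sqrt(n_sim)))
}

#' Effect as a percentage of the adjusted total association
#'
#' `100 * effect / total` on unrounded values.
#'
#' @param effect,total numeric effect estimates (percentage points).
#' @return percentage.
#' @export
percent_of_total <- function(effect, total) {
  if (any(total == 0)) stop("undefined ratio: total association is zero",
                            call. = FALSE)
  100 * effect / total
}
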