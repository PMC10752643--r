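---
title: "Interventional disparity mediation for stroke outcomes: models, estimator, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interventional disparity mediation for stroke outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intervmed)
```

## The scientific question

Patients of low socioeconomic status (SES) die or become dependent in
activities of daily living (ADL) after ischemic stroke more often than more
privileged patients. How much of that disparity could be removed by
realistic interventions on things that lie *between* SES and the outcome —
the comorbidity and medication profile a patient brings to the stroke, the
severity of the stroke itself (NIHSS > 5 versus ≤ 5), and the acute care
received (reperfusion therapy; stroke-unit care)?

`intervmed` implements an interventional-disparity mediation analysis for
this setting: a three-level SES exposure (`low`, `mid`, `high`, composed
from education and income tertile), two baseline confounders (sex and age),
eleven binary mediators in four causally ordered blocks, and a binary
outcome (dead or ADL dependent at three months). Because registry data of
this kind cannot be shipped, the package pairs the estimator with a fully
specified synthetic registry generator whose ground truth is exactly
enumerable, so every statistical property of the pipeline is testable.

## Estimands

Write $A$ for SES, $C = (\text{sex}, \text{age})$, $M$ for the joint
mediator vector and $Y$ for the outcome. All quantities are standardized
risks of the form

$$R(a, D) \;=\; \mathbb{E}_{C \sim F_{\text{low}}}\,
\mathbb{E}_{M \sim D(\cdot \mid C)}\, P(Y = 1 \mid A = a, M, C),$$

where $F_{\text{low}}$ is the confounder distribution of the low-SES group
(the disparity framing: every effect answers "what would change for
patients with low SES"; a whole-cohort standardization is available via
`standardization = "cohort"`). With $D_a$ the fitted joint mediator law at
SES level $a$ and $g$ the comparison level (`mid` or `high`):

* adjusted total association: $R(\text{low}, D_{\text{low}}) - R(g, D_g)$;
* indirect effect through all mediators:
  $R(\text{low}, D_{\text{low}}) - R(\text{low}, D_g)$ — the part of the
  disparity removable by giving low-SES patients the mediator distribution
  of group $g$;
* direct effect: $R(\text{low}, D_g) - R(g, D_g)$ — what would remain.

These are interventional (distribution-shifting) quantities: they do not
require cross-world counterfactuals, nor strong assumptions about the
ordering of the mediators among themselves.

Block-specific effects use *block-independent* mediator laws: for each of
the four blocks, one ancestral pass through the chain is run at that
block's source level and only that block's values are kept, so blocks are
mutually independent with their correct block marginals. Walking the source
levels from all-`low` to all-$g$ one causal block at a time
(comorbidities → severity → reperfusion → stroke-unit care) gives a
telescoping path $s_0, \dots, s_4$; the indirect effect of block $k$ is
$R(\text{low}, s_{k-1}) - R(\text{low}, s_k)$. The *dependence* effect —
the contribution of the mediators' mutual association beyond their
marginals — is
$[R(\text{low}, D_{\text{low}}) - R(\text{low}, s_0)] -
 [R(\text{low}, D_g) - R(\text{low}, s_4)]$.
By construction the identities

* direct + indirect(all) = total,
* sum of the four block indirects + dependence = indirect(all)

hold *exactly*, not just in expectation (see "Common random numbers").
The decomposition is order-dependent in principle; the block order is fixed
to the causal order, and a one-at-a-time reading of block effects can be
recovered by composing scenarios manually with `scenario()`.

## Models

All component models are logistic regressions built from one shared term
language (`model_spec()`, `build_design()`), so the fitting, simulation and
enumeration codepaths evaluate literally the same linear predictors:

* **outcome model**: `outcome ~ ses + sex + age + age² + 11 mediators`,
  plus interactions per the `interactions` mode;
* **sequential mediator models**: mediator $k$ on SES, sex, age + age², and
  mediators $1..k{-}1$ — jointly the chain-rule factorization
  $P(M \mid A, C)$ that the engine samples from;
* **marginal mediator models** (descriptive odds-ratio tables only).

The `interactions` mode controls flexibility. `"full"` adds
exposure-by-mediator *and* pairwise mediator-by-mediator products to the
outcome model (minus the anticoagulant–reperfusion pair, excluded because
that cell is far too sparse to support a product term — an exclusion that
only has meaning if mediator-by-mediator terms exist, which is why the
default includes them), and exposure-by-preceding-mediator terms to the
sequential models. `"exposure_only"` keeps just the exposure-by-mediator
products; `"none"` fits main effects. `"full"` is the default and the
right choice at registry scale (tens of thousands of records). At desk
scale the flexible models overfit: with $n = 2{,}000$ (~500 outcome
events) a 90-column outcome model has fewer than 6 events per parameter,
and in our recovery experiments it biased the direct/indirect split by
more than a percentage point. The package's simulation suites therefore
fit main-effects models at $n = 2{,}000$, which is the standard
events-per-variable prescription, and the flexible default at registry
scale.

Fitting is maximum likelihood via iteratively reweighted least squares
(`stats::glm.fit`), relative-deviance tolerance `1e-8`, at most 100
iterations. Separation is flagged at |coefficient| > 15 on the log-odds
scale. Rank-deficient designs drop aliased columns with a warning — inside
bootstrap replicates this is essential, since resampling routinely empties
a sparse interaction cell; aborting there would make B = 1,000 infeasible.
Age is centered at 70 years before squaring (predictions are invariant to
the centering; it exists purely for numerical conditioning). SES is
treatment-coded with `low` as reference, so disparity contrasts read
directly off coefficients; odds-ratio tables negate coefficients where a
"low vs other" presentation is wanted. Wald 95% intervals throughout.

## The simulation estimator and common random numbers

`estimate_disparity_effects()` evaluates each $R(a, D)$ by Monte Carlo:
for each of `n_sim` repetitions (default 200) it draws one mediator vector
per standardization row by ancestral sampling — mediator $j$ is the
indicator $u_{ij} < \hat p_j(\cdot)$ — evaluates the outcome model, and
averages; the estimate is the grand mean over repetitions.

One uniform stream, laid out as (repetition × row × mediator) plus one
auxiliary stream per block pass, is shared by *every* scenario. This is a
deliberate design choice the estimand definitions do not force:

* the decomposition identities above hold exactly (to floating point),
  because the scenario risks telescope over identical draws;
* scenarios whose mediator laws coincide produce *identical* draws, so
  null indirect effects are exactly zero rather than small noise;
* the Monte-Carlo variance of every contrast collapses, since draw noise is
  common to both arms.

The per-effect `mc_se` reported alongside point estimates is the
Monte-Carlo standard error of the simulation step only (computed from the
per-repetition contrasts); it is *not* statistical uncertainty — that comes
from the bootstrap.

## The enumeration oracle

With eleven binary mediators, every inner expectation is a sum over the
$2^{11} = 2{,}048$ mediator configurations weighted by chain-rule
probabilities (joint laws) or by products of exactly marginalized block
laws (block-independent laws). `enumerate_disparity_effects()` runs the
identical estimand algebra with those exact sums — zero Monte-Carlo
error — and is the package's verification oracle for the simulation
engine. `true_effects()` applies the same enumeration to the structural
equations of a synthetic configuration, integrating the outer expectation
over sex exactly and over age by 64-point Gauss–Legendre quadrature against
the truncated-normal age density (the node count is a documented,
configurable constant; 64 nodes are far past convergence for these smooth
logistic integrands).

## The synthetic registry

`default_dgp()` is a fixed, versioned configuration emulating a national
ischemic-stroke register cohort (2015–2016, patients ADL-independent before
the stroke): SES drawn with shares 16.0 / 71.1 / 12.9%, sex and
truncated-normal age (18–105 years; means 80.5 / 73.9 / 70.3, SDs 10.7 /
11.6 / 12.5 by descending SES) per group, then the eleven mediators by
ancestral sampling in block order, the outcome, and three auxiliary
variables. Design points:

* **Calibration.** The published cohort characteristics shipped in
  `inst/extdata/registry_targets.csv` pin down, per SES group, the
  prevalence of every mediator and of the outcome. The per-group intercept
  offsets of every structural equation are solved by exact enumeration
  (`calibrate_dgp_offsets()`, rerunnable via `analysis/00_calibrate_dgp.R`)
  so the implied prevalences match those targets; the solved constants are
  frozen in the package source. Slopes (age, sex, and mediator-mediator
  dependence) are *not* identified by the targets and are fixed at
  clinically plausible magnitudes: anticoagulation driven strongly by
  atrial fibrillation, reperfusion more likely for severe strokes and less
  likely under anticoagulation, severity dominating the outcome equation
  (log-odds ≈ 2.15), a modest protective reperfusion effect, and a small
  negative severity-by-reperfusion outcome interaction. Within-block
  comorbidity dependence is induced by letting each comorbidity's equation
  include previously generated comorbidities, with small positive
  coefficients; the published tables say nothing about within-block
  structure, so these are plausible but uncalibrated — which also means the
  synthetic dependence effect need not match any published magnitude.
* **Auxiliaries.** Level of consciousness (RLS > 1), ambulance arrival and
  onset-to-door time are generated from severity and acute care, so they
  carry real information about a missing severity value — the property that
  makes them useful imputation auxiliaries.
* **Missingness.** `inject_missingness()` makes `severe` missing via a
  logistic model in reperfusion, stroke-unit care, sex, age and the
  auxiliaries — observed variables only, hence missing-at-random by
  construction (a mechanism referencing severity itself is rejected). The
  intercept is solved at injection time so the expected missing fraction
  equals the target (default 41.8%).

What the generator does *not* emulate: income in kronor or education
trajectories (SES is drawn directly as a 3-level factor), hospital-level
clustering, non-response at follow-up, measurement error in NIHSS, or any
departure from logistic structural forms. Passing tests on this generator
therefore demonstrate the estimator's internal correctness and its behavior
under a realistic, known data-generating law — not robustness to the
misspecifications real registry data would add.

## Uncertainty: bootstrap, multiple imputation, Rubin's rules

**Bootstrap.** `bootstrap_mediation()` resamples records with replacement
(default B = 1,000), refits all twelve models on each replicate
(warm-started; replicate refits use a relaxed IRLS tolerance of `1e-6`,
far below bootstrap noise), and re-estimates the effects with
`n_sim_boot` draws (defaults to `n_sim`; reducible to 50 for desk-scale
runs — the common-random-number contrasts keep the added Monte-Carlo noise
small relative to sampling noise). SE = replicate standard deviation;
intervals are Wald intervals around the original-sample point estimate,
matching the symmetric intervals a "standard errors from B replicates"
presentation implies; percentile intervals can be read off the replicate
matrix returned in the `replicates` attribute. Replicates that fail
(degenerate resample) are counted and reported; more than 10% failures is
an error, never silent.

**Multiple imputation.** Only `severe` is ever missing in analysis data
(everything else is removed up front by `complete_case_filter()`, matching
the complete-case-except-NIHSS design), so imputation is a single logistic
model, not chained equations: severity regressed on all analysis variables
plus the three auxiliaries, with age² and all two-way interactions among
exposure, mediators and outcome except anticoagulant–reperfusion.
Imputation is *proper*: each of the m datasets uses a coefficient vector
drawn from the asymptotic normal posterior (mean = MLE, covariance =
inverse information, symmetric eigenvalue square root for robustness near
singularity), then Bernoulli draws for the missing values. Default
m = 45, following the rule that the number of imputations should be at
least the percentage of missing data (~42%). If the rich interaction
model separates or fails — likely in small synthetic cohorts — the
imputation falls back to main effects with a warning.

**Composition.** `mi_analysis()` nests the bootstrap *within* each imputed
dataset and pools per effect by Rubin's rules:
$\bar Q = \tfrac1m\sum \hat Q_i$, $T = \bar W + (1 + 1/m)B_m$. Two
deliberate choices: (i) the simulation stream and the bootstrap resampling
indices are shared across imputations, so between-imputation variance
reflects imputation uncertainty alone — and at zero missingness the pooled
analysis reproduces the complete-data pipeline bit for bit; (ii) pooled
intervals use the normal reference rather than the Barnard–Rubin
small-sample degrees of freedom, negligible at registry scale with
m = 45. Percent-of-total values are pooled from the per-imputation ratios
with their bootstrap variances.

**Seeds.** Every stage derives named child seeds from one master seed
(`derive_seed()`, a documented 31-bit hash), so generation, missingness,
imputation, simulation and bootstrap can be rerun independently and every
pipeline output is deterministic given its configuration.

## Numerical conventions

* Effects are computed and stored unrounded, in percentage points; display
  uses one decimal, ties rounded half away from zero (matching the
  convention of the published tables this package's layouts mirror), with
  the sign preserved on values that round to zero (`-0.0`).
* Odds ratios display at two decimals; p-values below 0.001 print
  `<0.001`.
* CSV round-trips are lossless: ages are written with 17 significant
  digits, and the generator itself rounds ages to two decimals so written
  cohorts are bit-stable.

## Problem sizes used by the test suites

The verification suites run at sizes chosen to exercise every property at
desk scale: exact-identity and null-exactness checks on cohorts of 500 to
5,000; simulation-versus-enumeration agreement on ~500 standardization rows
with 2,000 draws; estimator recovery on 100 cohorts of n = 2,000 against
enumerated truth (main-effects models, per the events-per-variable argument
above); bootstrap coverage of the total association on 50 of those cohorts
with B = 200; the missing-data experiment on 20 cohorts of n = 4,000 at
41.8% missingness with m = 10. The worked registry-scale pipeline
(n = 25,846) in `analysis/` and `scripts/acceptance.R` uses m = 10
imputations and point estimates at the full 200 draws.

One finite-sample behavior of the full pipeline deserves flagging. On the
synthetic registry the *conditional* SES–severity association (given sex,
age and comorbidities) is deliberately small — most of the severity
gradient across SES runs through age and comorbidity differences, as the
calibration targets imply. Imputing 42% of severity values from a logistic
model necessarily approximates the true conditional law
$P(\text{severe} \mid \text{everything else})$ of the generator, which
contains structure no 2-way-interaction logistic can represent (including,
ironically, the excluded anticoagulant–reperfusion cell); the residual
misspecification washes a few hundredths of a log-odds out of the fitted
SES coefficients of the severity model. Group-level severity prevalences
are preserved almost exactly (the behavior the missing-data experiment
verifies), but the post-imputation severity block indirect at desk scale
shifts part of its weight into the direct effect relative to the
enumerated complete-data truth. This is a property of imputing a weakly
SES-conditioned mediator at a 42% missing fraction, not of the estimator:
the complete-data pipeline recovers the enumerated truth within sampling
error at every scale tested.

## Known limitations

* Identification rests on no unmeasured confounding of the
  mediator–outcome relationships given SES, sex and age — untestable, and
  surely optimistic with only two baseline confounders.
* Binary mediators only; the severity dichotomy (NIHSS > 5) discards
  within-scale information, and a different cutoff could shift the
  decomposition.
* The block decomposition is tied to the declared causal block order;
  alternative orders change the telescoping path (the joint indirect and
  direct effects are order-invariant).
* Natural direct/indirect effects, continuous mediators, hospital-level
  adjustment and penalized fitting are out of scope.
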