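#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that package functions are
#' deterministic given their `seed` argument without disturbing the caller's
#' random-number stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a named child seed from a master seed
#'
#' Deterministic hash of `(master, label)` into \[1, 2^31 - 2\] so that the
#' pipeline stages (generation, missingness, imputation, simulation,
#' bootstrap) can be re-run independently from one master seed.
#'
#' @param master integer master seed.
#' @param label character stage label.
#' @return integer seed.
#' @export
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(label))
  m <- 2147483629 # largest prime below 2^31
  x <- as.double(master) %% m
  for (ch in utf8ToInt(label)) x <- (x * 31 + ch) %% m
  as.integer(x %% (m - 2L)) + 1L
}

#' Round half away from zero
#'
#' Commercial rounding used for all printed percentages and effect tables:
#' ties go away from zero (`0.05 -> 0.1`), unlike [round()]'s banker's
#' rounding. A tiny epsilon guards against binary-representation error in
#' values such as `0.345 * 10`.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector (sign of exact zeros is preserved).
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Format a count with a within-group percentage
#'
#' Renders `"1,619 (39.2)"`-style cells: thousands-separated count and the
#' percentage to one decimal, rounded half-up.
#'
#' @param count integer count.
#' @param denom integer denominator (non-missing records in the group).
#' @return character vector.
#' @export
fmt_count_pct <- function(count, denom) {
  denom <- rep_len(denom, length(count))
  pct <- ifelse(denom > 0, round_half_up(100 * count / denom, 1), 0)
  sprintf("%s (%s)", formatC(count, format = "d", big.mark = ","),
          formatC(pct, format = "f", digits = 1))
}

# one-decimal effect formatting; keeps the sign on values that round to zero
fmt_effect1 <- function(x) {
  out <- formatC(round_half_up(x, 1), format = "f", digits = 1)
  neg0 <- x < 0 & out == "0.0"
  out[neg0] <- "-0.0"
  out
}

fmt_or2 <- function(x) formatC(round_half_up(x, 2), format = "f", digits = 2)

fmt_p <- function(p) ifelse(p < 0.001, "<0.001", formatC(round_half_up(p, 3), format = "f", digits = 3))

#' Gauss-Legendre nodes and weights
#'
#' Golub-Welsch computation of the n-point Gauss-Legendre rule on
#' \eqn{[a, b]}; used to integrate smooth functions of age against the
#' truncated-normal age density in the enumeration oracle.
#'
#' @param n number of nodes.
#' @param a,b interval endpoints.
#' @return list with `nodes` and `weights`.
#' @keywords internal
gauss_legendre <- function(n, a = -1, b = 1) {
  if (n == 1L) {
    x <- 0
    w <- 2
  } else {
    k <- seq_len(n - 1)
    beta <- k / sqrt(4 * k^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(k, k + 1)] <- beta
    J[cbind(k + 1, k)] <- beta
    e <- eigen(J, symmetric = TRUE)
    ord <- order(e$values)
    x <- e$values[ord]
    w <- 2 * e$vectors[1, ord]^2
  }
  list(nodes = (b - a) / 2 * x + (a + b) / 2, weights = (b - a) / 2 * w)
}

# weighted quadrature grid for a normal(mean, sd) truncated to (lo, hi)
truncnorm_grid <- function(n, mean, sd, lo, hi) {
  gl <- gauss_legendre(n, lo, hi)
  dens <- stats::dnorm(gl$nodes, mean, sd)
  w <- gl$weights * dens
  list(nodes = gl$nodes, weights = w / sum(w))
}
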