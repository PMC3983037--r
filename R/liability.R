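#' Liability-threshold model for an ascertained case-control study
#'
#' Quantities of the liability-threshold model for a disease with population
#' prevalence `K` studied in a sample containing a proportion `v` of cases.
#' Disease liability is modelled as a standard normal variable; individuals
#' whose liability exceeds the threshold `t = qnorm(1 - K)` are affected.
#' The model carries the constant `c` that linearly relates heritability
#' (and hence its standard error) on the observed 0/1 scale to the
#' unobserved liability scale under ascertainment,
#' \deqn{c = \frac{K^2 (1-K)^2}{z^2\, v(1-v)} = \frac{(1-K)^2}{i^2\, v(1-v)},}
#' where `z` is the standard normal density at the threshold and
#' `i = z/K` is the selection intensity (mean liability of cases).
#'
#' At `K = v = 0.5` the factor reduces to `pi/2`.  For rare diseases with
#' balanced ascertainment (`v = 0.5`, small `K`) the factor drops below 1:
#' oversampling cases concentrates information about liability-scale
#' variance, so the liability-scale standard error shrinks relative to the
#' observed scale and power increases.
#'
#' @param K Disease prevalence in the population; `0 < K < 1`.  Values
#'   within `1e-6` of 0 or 1 are rejected as numerically fragile and
#'   outside the regime in which the transformation is used.
#' @param v Proportion of cases in the analysed sample; `0 < v < 1`.
#'   `K` and `v` are independent design knobs: `v` is set by ascertainment,
#'   not by prevalence, so both must be supplied.
#'
#' @return An object of class `liability_model`: a list with elements
#'   `K`, `v`, `t` (liability threshold), `z` (normal density at `t`),
#'   `i` (selection intensity `z/K`) and `c` (observed-to-liability
#'   conversion factor).
#'
#' @examples
#' liability_model(K = 0.5, v = 0.5)$c   # pi/2
#' liability_model(K = 0.01, v = 0.5)    # a typical psychiatric design
#' @seealso [h2_obs_to_liab()], [h2_liab_to_obs()], [se_h2_cc_liab()]
#' @export
liability_model <- function(K, v) {
  check_probability(K, "K", tol = 1e-6)
  check_probability(v, "v", tol = 1e-6)
  t <- stats::qnorm(1 - K)
  z <- stats::dnorm(t)
  i <- z / K
  c_factor <- K^2 * (1 - K)^2 / (z^2 * v * (1 - v))
  structure(
    list(K = K, v = v, t = t, z = z, i = i, c = c_factor),
    class = "liability_model"
  )
}

#' @export
print.liability_model <- function(x, ...) {
  cat("Liability-threshold model\n")
  cat(sprintf("  prevalence K        : %g\n", x$K))
  cat(sprintf("  case proportion v   : %g\n", x$v))
  cat(sprintf("  threshold t         : %.6f\n", x$t))
  cat(sprintf("  density z = phi(t)  : %.6f\n", x$z))
  cat(sprintf("  selection int. i=z/K: %.6f\n", x$i))
  cat(sprintf("  obs -> liab factor c: %.6f\n", x$c))
  invisible(x)
}

#' Convert heritability between the observed and liability scales
#'
#' Linear conversion of the proportion of variance captured by SNPs between
#' the observed 0/1 disease scale and the underlying liability scale, using
#' the ascertainment-aware factor `c` of a [liability_model()]:
#' `h2_liab = c * h2_obs`.  Because the transformation is linear, standard
#' errors convert by the same factor and the two functions are exact
#' inverses of one another.
#'
#' @param h2_obs,h2_liab Non-negative heritability on the source scale.
#' @param model A [liability_model()].
#' @return The heritability on the target scale.
#' @examples
#' m <- liability_model(K = 0.01, v = 0.5)
#' h2_obs_to_liab(0.41, m)   # observed-scale 0.41 maps to ~0.23 liability
#' @export
h2_obs_to_liab <- function(h2_obs, model) {
  stopifnot(inherits(model, "liability_model"))
  if (any(!is.finite(h2_obs)) || any(h2_obs < 0)) {
    stop("`h2_obs` must be finite and >= 0", call. = FALSE)
  }
  h2_obs * model$c
}

#' @rdname h2_obs_to_liab
#' @export
h2_liab_to_obs <- function(h2_liab, model) {
  stopifnot(inherits(model, "liability_model"))
  if (any(!is.finite(h2_liab)) || any(h2_liab < 0)) {
    stop("`h2_liab` must be finite and >= 0", call. = FALSE)
  }
  h2_liab / model$c
}

# shared parameter validation -------------------------------------------------

check_probability <- function(x, name, tol = 0) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (x <= tol || x >= 1 - tol) {
    stop(sprintf("`%s` must lie strictly in (%g, %g); got %g",
                 name, tol, 1 - tol, x), call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, name, min = 1) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x) ||
      x < min || x != round(x)) {
    stop(sprintf("`%s` must be an integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

check_positive <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive number", name), call. = FALSE)
  }
  invisible(x)
}
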