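#' Non-centrality parameter of the Wald test
#'
#' The Wald statistic \eqn{(\hat\theta/\mathrm{SE})^2} for
#' \eqn{\theta \in \{h^2_{SNP}, r_G\}} is asymptotically non-central
#' \eqn{\chi^2_1} with non-centrality parameter
#' \eqn{\lambda = \theta^2/\mathrm{var}(\hat\theta)}.
#'
#' @param theta Parameter value under the alternative.
#' @param var_theta Sampling variance of its estimate; must be positive.
#' @return The non-centrality parameter \eqn{\lambda \ge 0}.
#' @examples
#' ncp(0.2, var_h2_qt(4430))
#' @export
ncp <- function(theta, var_theta) {
  if (any(!is.finite(var_theta)) || any(var_theta <= 0)) {
    stop("`var_theta` must be positive and finite", call. = FALSE)
  }
  theta^2 / var_theta
}

#' Power of the one-degree-of-freedom chi-squared test
#'
#' Probability that a non-central \eqn{\chi^2_1(\lambda)} variable exceeds
#' the central \eqn{\chi^2_1} critical value at type-I error rate `alpha`
#' (a two-sided Wald test).  At `lambda = 0` this is the size of the test,
#' `alpha`; it increases strictly to 1 as `lambda` grows.
#'
#' @param lambda Non-centrality parameter, `>= 0`.
#' @param alpha Type-I error rate, in (0, 1).
#' @return The statistical power.
#' @examples
#' power_from_ncp(0, 0.05)       # = alpha
#' power_from_ncp(7.849, 0.05)   # ~ 0.80
#' @export
power_from_ncp <- function(lambda, alpha = 0.05) {
  stopifnot(all(lambda >= 0), all(alpha > 0), all(alpha < 1))
  q <- stats::qchisq(1 - alpha, df = 1)
  stats::pchisq(q, df = 1, ncp = lambda, lower.tail = FALSE)
}

#' Power of a GREML design
#'
#' Composes the design's sampling-variance approximation with the
#' non-central \eqn{\chi^2_1} test: \eqn{\lambda = \theta^2/\mathrm{var}
#' (\hat\theta)} with \eqn{\theta = h^2} (quantitative trait),
#' \eqn{h^2_L} (case-control; power is invariant to expressing the design
#' on the observed or the liability scale, since \eqn{\theta} and its SE
#' transform by the same linear factor) or \eqn{r_G} (bivariate).
#'
#' @param design A [qt_design()], [cc_design()] (with a heritability set)
#'   or [bv_design()].
#' @param alpha Type-I error rate.
#' @return An object of class `power_result`: list with `theta`, `se`,
#'   `ncp`, `alpha`, `power`.
#' @examples
#' greml_power(qt_design(4500, h2 = 0.2))
#' @export
greml_power <- function(design, alpha = 0.05) {
  stopifnot(inherits(design, "greml_design"))
  theta <- design_theta(design)
  if (is.na(theta)) {
    stop("the design has no parameter value (h2 / rg) to test", call. = FALSE)
  }
  se <- design_se(design)
  lambda <- ncp(theta, se^2)
  structure(
    list(theta = theta, se = se, ncp = lambda, alpha = alpha,
         power = power_from_ncp(lambda, alpha)),
    class = "power_result"
  )
}

#' @export
print.power_result <- function(x, ...) {
  cat("GREML power calculation (Wald chi-squared, 1 df)\n")
  cat(sprintf("  theta = %g, SE = %.6g (%.3f)\n", x$theta, x$se, x$se))
  cat(sprintf("  NCP   = %.4f, alpha = %g\n", x$ncp, x$alpha))
  cat(sprintf("  power = %.6g (%.3f)\n", x$power, x$power))
  invisible(x)
}

#' Minimum sample size for a target power
#'
#' Smallest sample size whose Wald-test power reaches `target_power`.
#' Because the non-centrality parameter grows monotonically (quadratically,
#' for univariate designs) with sample size, the continuous solution is
#' found by bisection and then rounded up: `rounding = "none"` returns the
#' smallest integer sample size meeting the target, `"ceil_100"` (the
#' default reporting convention) rounds up to the next multiple of 100.
#' The achieved power at the returned size is re-evaluated and reported.
#'
#' For a case-control design the case proportion `v` is held fixed while
#' the total is scaled; for a two-sample bivariate design the `N2/N1`
#' ratio is held fixed and the returned value is the total `N1 + N2`
#' (with the per-sample split also reported).
#'
#' @param design A design object with a nonzero parameter value.
#' @param target_power Desired power, in (0, 1).
#' @param alpha Type-I error rate.
#' @param rounding `"ceil_100"` or `"none"`.
#' @return An object of class `min_n_result`: list with `n` (reported
#'   minimum), `n_unrounded` (smallest integer solution), `n_exact`
#'   (continuous solution), `power` at `n`, and for two-sample designs
#'   `n1`, `n2`.
#' @examples
#' min_n_for_power(qt_design(1000, h2 = 0.1))$n   # 8900
#' @export
min_n_for_power <- function(design, target_power = 0.80, alpha = 0.05,
                            rounding = c("ceil_100", "none")) {
  rounding <- match.arg(rounding)
  stopifnot(inherits(design, "greml_design"),
            target_power > 0, target_power < 1)
  theta <- design_theta(design)
  if (is.na(theta) || theta == 0) {
    stop("no finite sample size reaches the target power when theta = 0",
         call. = FALSE)
  }
  power_at <- function(n) {
    greml_power(design_at_n(design, n), alpha = alpha)$power
  }
  lo <- 2
  hi <- 100
  while (power_at(hi) < target_power) {
    hi <- hi * 2
    if (hi > 1e10) stop("no attainable sample size below 1e10", call. = FALSE)
  }
  if (power_at(lo) >= target_power) {
    n_exact <- lo
  } else {
    n_exact <- stats::uniroot(function(n) power_at(n) - target_power,
                              c(lo, hi), tol = 1e-8)$root
  }
  n_int <- ceiling(n_exact - 1e-9)
  n_rep <- if (rounding == "ceil_100") 100 * ceiling(n_int / 100) else n_int
  achieved <- power_at(n_rep)
  stopifnot(achieved >= target_power)
  out <- list(n = n_rep, n_unrounded = n_int, n_exact = n_exact,
              power = achieved, alpha = alpha,
              target_power = target_power, rounding = rounding)
  if (inherits(design, "bv_design") && design$mode == "different_samples") {
    f1 <- design$n1 / (design$n1 + design$n2)
    out$n1 <- ceiling(f1 * n_rep)
    out$n2 <- n_rep - out$n1
  }
  structure(out, class = "min_n_result")
}

#' @export
print.min_n_result <- function(x, ...) {
  cat(sprintf(
    "Minimum sample size for power >= %g at alpha = %g: %d (%s)\n",
    x$target_power, x$alpha, as.integer(x$n),
    if (x$rounding == "ceil_100") "rounded up to next 100" else "unrounded"))
  cat(sprintf("  unrounded: %d (continuous solution %.1f), achieved power %.4f\n",
              as.integer(x$n_unrounded), x$n_exact, x$power))
  if (!is.null(x$n1)) {
    cat(sprintf("  split: n1 = %d, n2 = %d\n",
                as.integer(x$n1), as.integer(x$n2)))
  }
  invisible(x)
}

#' Power as a function of sample size
#'
#' Evaluates the standard error, non-centrality parameter and power of a
#' design over a grid of sample sizes (total cases + controls for a
#' case-control design; total `N1 + N2` at fixed ratio for a two-sample
#' bivariate design).
#'
#' @param design A design object with a parameter value set.
#' @param n_grid Vector of positive sample sizes.
#' @param alpha Type-I error rate.
#' @return A data frame with columns `n`, `se`, `ncp`, `power`; power is
#'   non-decreasing along increasing `n`.
#' @examples
#' power_curve(qt_design(1000, h2 = 0.2), n_grid = seq(1000, 8000, 1000))
#' @export
power_curve <- function(design, n_grid, alpha = 0.05) {
  stopifnot(inherits(design, "greml_design"), length(n_grid) >= 1,
            all(n_grid >= 2))
  rows <- lapply(sort(n_grid), function(n) {
    p <- greml_power(design_at_n(design, n), alpha = alpha)
    data.frame(n = n, se = p$se, ncp = p$ncp, power = p$power)
  })
  do.call(rbind, rows)
}
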