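#' Study designs for GREML power and sampling-variance calculations
#'
#' Parameter bundles describing the three study designs the closed-form
#' sampling-variance approximations cover: a univariate analysis of a
#' quantitative trait, a univariate case-control study, and a bivariate
#' analysis of two traits measured on the same or on different samples.
#' Design objects are consumed by [se_h2()], [se_rg()], [greml_power()],
#' [min_n_for_power()] and [power_curve()].
#'
#' `var_pi` is the variance of the off-diagonal entries of the SNP-derived
#' genetic relationship matrix among conventionally unrelated individuals.
#' It is approximately `2e-5` for genome-wide coverage of common SNPs in
#' human populations and is the key constant scaling every sampling
#' variance; it changes with the SNP set and GRM construction, so it is an
#' explicit parameter of every design (use [empirical_var_pi()] to measure
#' it from data).
#'
#' @param n,n_case,n_control Numbers of (unrelated) individuals.
#' @param h2 SNP heritability of the quantitative trait.  Used only for
#'   power calculations; the standard error itself is independent of `h2`.
#' @param h2_liab,h2_obs Liability-scale / observed-scale SNP heritability
#'   of the disease.  Supply either; the other is derived through the
#'   liability model.  Used only for power.
#' @param K Disease prevalence in the population.
#' @param v Proportion of cases in the sample; defaults to
#'   `n_case / (n_case + n_control)`.
#' @param var_pi Variance of off-diagonal SNP-derived relatedness.
#'
#' @return An object of class `qt_design`, `cc_design` or `bv_design`
#'   (all also of class `greml_design`).
#' @examples
#' qt_design(n = 3925)
#' cc_design(n_case = 1604, n_control = 1953, K = 0.001)
#' @name greml_design
NULL

#' @rdname greml_design
#' @export
qt_design <- function(n, h2 = NA_real_, var_pi = 2e-5) {
  check_positive(n, "n")
  if (n < 2) stop("`n` must be at least 2", call. = FALSE)
  check_positive(var_pi, "var_pi")
  if (!is.na(h2)) check_h2_range(h2, "h2")
  structure(list(n = n, h2 = h2, var_pi = var_pi),
            class = c("qt_design", "greml_design"))
}

#' @rdname greml_design
#' @export
cc_design <- function(n_case, n_control, K, v = NULL,
                      h2_liab = NA_real_, h2_obs = NA_real_,
                      var_pi = 2e-5) {
  check_positive(n_case, "n_case")
  check_positive(n_control, "n_control")
  check_positive(var_pi, "var_pi")
  if (is.null(v)) v <- n_case / (n_case + n_control)
  model <- liability_model(K, v)
  if (!is.na(h2_liab) && !is.na(h2_obs)) {
    if (abs(h2_obs_to_liab(h2_obs, model) - h2_liab) > 1e-8) {
      stop("`h2_liab` and `h2_obs` are inconsistent with the liability model",
           call. = FALSE)
    }
  } else if (!is.na(h2_liab)) {
    check_h2_range(h2_liab, "h2_liab")
    h2_obs <- h2_liab_to_obs(h2_liab, model)
  } else if (!is.na(h2_obs)) {
    h2_liab <- h2_obs_to_liab(h2_obs, model)
  }
  structure(
    list(n_case = n_case, n_control = n_control, n = n_case + n_control,
         K = K, v = v, model = model,
         h2_liab = h2_liab, h2_obs = h2_obs, var_pi = var_pi),
    class = c("cc_design", "greml_design")
  )
}

#' Bivariate study design for a genetic-correlation analysis
#'
#' Describes a bivariate GREML analysis of two traits, each quantitative
#' ([qt_design()]) or case-control ([cc_design()]), measured either on the
#' same individuals (`mode = "same_sample"`) or on disjoint samples
#' (`mode = "different_samples"`).  Case-control traits enter the
#' genetic-correlation variance formulas through their observed-scale
#' heritability (the liability transformation is linear, so the estimated
#' correlation itself is scale-invariant).
#'
#' @param trait1,trait2 [qt_design()] or [cc_design()] objects.  Their
#'   sample sizes give `N` (same sample; the two must agree) or
#'   `N1`, `N2` (different samples), and their heritabilities must be
#'   positive (the correlation variance divides by them).
#' @param rg Genetic correlation parameter, in `[-1, 1]`.
#' @param mode `"same_sample"` or `"different_samples"`.
#' @param rp Phenotypic correlation between the two traits in the same
#'   individuals.  Required in same-sample mode (it has no defensible
#'   default) and forbidden in different-samples mode, where the residual
#'   covariance between disjoint unrelated samples is zero by assumption.
#' @param var_pi Variance of off-diagonal SNP-derived relatedness; must
#'   agree between the traits' designs if set there.
#' @return An object of class `bv_design`.
#' @examples
#' scz <- cc_design(9032, 7980, K = 0.01, h2_obs = 0.40)
#' bpd <- cc_design(6664, 5258, K = 0.01, h2_obs = 0.39)
#' bv_design(scz, bpd, rg = 0.68, mode = "different_samples")
#' @export
bv_design <- function(trait1, trait2, rg,
                      mode = c("same_sample", "different_samples"),
                      rp = NULL, var_pi = 2e-5) {
  mode <- match.arg(mode)
  stopifnot(inherits(trait1, "greml_design"), inherits(trait2, "greml_design"))
  if (length(rg) != 1L || !is.finite(rg) || abs(rg) > 1) {
    stop("`rg` must be a single number in [-1, 1]", call. = FALSE)
  }
  check_positive(var_pi, "var_pi")
  h2_1 <- analysis_scale_h2(trait1)
  h2_2 <- analysis_scale_h2(trait2)
  for (h in c(h2_1, h2_2)) {
    if (is.na(h)) stop("both traits need a heritability for a bivariate design",
                       call. = FALSE)
    if (h <= 0) stop("trait heritability must be > 0: the genetic-correlation ",
                     "variance divides by h2", call. = FALSE)
    if (h < 0.001) warning("trait heritability < 0.001: the approximation is ",
                           "unreliable this close to zero")
  }
  if (mode == "same_sample") {
    if (trait1$n != trait2$n) {
      stop("same-sample mode requires the two traits to share one sample ",
           "(equal n)", call. = FALSE)
    }
    if (is.null(rp)) {
      stop("`rp` (phenotypic correlation) is required in same-sample mode",
           call. = FALSE)
    }
    if (length(rp) != 1L || !is.finite(rp) || abs(rp) > 1) {
      stop("`rp` must be a single number in [-1, 1]", call. = FALSE)
    }
  } else {
    if (!is.null(rp)) {
      stop("`rp` must not be supplied in different-samples mode: the residual ",
           "covariance between disjoint samples is ignored", call. = FALSE)
    }
  }
  structure(
    list(trait1 = trait1, trait2 = trait2,
         mode = mode, rg = rg, rp = rp,
         h2_1 = h2_1, h2_2 = h2_2,
         n = if (mode == "same_sample") trait1$n else NA_real_,
         n1 = trait1$n, n2 = trait2$n, var_pi = var_pi),
    class = c("bv_design", "greml_design")
  )
}

# h2 on the scale the (co)variance analysis runs on: trait scale for a
# quantitative trait, observed 0/1 scale for a case-control trait.
analysis_scale_h2 <- function(trait) {
  if (inherits(trait, "cc_design")) trait$h2_obs else trait$h2
}

check_h2_range <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must lie in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

# Rescale a design to a new total sample size, preserving its structure
# (case proportion for case-control, N2/N1 ratio for two-sample bivariate).
# Sample sizes are treated as continuous here; used by the power solver.
design_at_n <- function(design, n_total) UseMethod("design_at_n")

design_at_n.qt_design <- function(design, n_total) {
  design$n <- n_total
  design
}

design_at_n.cc_design <- function(design, n_total) {
  design$n <- n_total
  design$n_case <- design$v * n_total
  design$n_control <- (1 - design$v) * n_total
  design
}

design_at_n.bv_design <- function(design, n_total) {
  if (design$mode == "same_sample") {
    design$n <- design$n1 <- design$n2 <- n_total
  } else {
    f1 <- design$n1 / (design$n1 + design$n2)
    design$n1 <- f1 * n_total
    design$n2 <- (1 - f1) * n_total
  }
  design
}

# parameter under test and its standard error, on a common scale ------------

design_theta <- function(design) UseMethod("design_theta")
design_theta.qt_design <- function(design) design$h2
design_theta.cc_design <- function(design) design$h2_liab
design_theta.bv_design <- function(design) design$rg

design_se <- function(design) UseMethod("design_se")
design_se.qt_design <- function(design) se_h2_qt(design$n, design$var_pi)
design_se.cc_design <- function(design) {
  se_h2_cc_liab(design$n_case, design$n_control, design$K, design$v,
                design$var_pi)
}
design_se.bv_design <- function(design) se_rg(design)

#' @export
print.qt_design <- function(x, ...) {
  cat(sprintf("Quantitative-trait GREML design: n = %g, h2 = %s, var_pi = %g\n",
              x$n, format(x$h2), x$var_pi))
  invisible(x)
}

#' @export
print.cc_design <- function(x, ...) {
  cat(sprintf(
    "Case-control GREML design: %g cases / %g controls (v = %.3f), K = %g\n",
    x$n_case, x$n_control, x$v, x$K))
  cat(sprintf("  h2 liability = %s, h2 observed = %s, var_pi = %g\n",
              format(x$h2_liab), format(x$h2_obs), x$var_pi))
  invisible(x)
}

#' @export
print.bv_design <- function(x, ...) {
  cat(sprintf("Bivariate GREML design (%s): rg = %g%s\n",
              gsub("_", " ", x$mode), x$rg,
              if (!is.null(x$rp)) sprintf(", rp = %g", x$rp) else ""))
  cat(sprintf("  trait 1: n = %g, analysis-scale h2 = %g\n", x$n1, x$h2_1))
  cat(sprintf("  trait 2: n = %g, analysis-scale h2 = %g\n", x$n2, x$h2_2))
  invisible(x)
}
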