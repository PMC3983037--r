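#' Sampling variance of the SNP-heritability estimate
#'
#' Closed-form approximation to the sampling variance of the GREML/HE
#' estimate of the proportion of phenotypic variance captured by all SNPs
#' in a sample of conventionally unrelated individuals,
#' \deqn{\mathrm{var}(\hat h^2) \approx \frac{2}{N^2\,\mathrm{var}(\pi)},}
#' where `var_pi` is the variance of off-diagonal SNP-derived relatedness.
#' The approximation follows from the asymptotic equivalence of REML to a
#' regression of pairwise phenotype products on pairwise relatedness over
#' the \eqn{N(N-1)/2} contrasts, and is independent of the heritability
#' itself and of any other property of the phenotype.  The same expression
#' applies unchanged to the observed 0/1 scale of a case-control study
#' with `N` the total number of cases and controls.
#'
#' @param n Sample size (number of unrelated individuals).
#' @param n_case,n_control Case and control counts.
#' @param var_pi Variance of off-diagonal SNP-derived relatedness
#'   (default `2e-5`, genome-wide common SNPs).
#' @return The sampling variance (`var_*`) or standard error (`se_*`).
#' @examples
#' se_h2_qt(3925)    # 0.081
#' se_h2_qt(11586)   # 0.027
#' se_h2_cc_obs(1604, 1953)  # 0.089
#' @export
var_h2_qt <- function(n, var_pi = 2e-5) {
  stopifnot(all(n >= 2), all(var_pi > 0))
  2 / (n^2 * var_pi)
}

#' @rdname var_h2_qt
#' @export
se_h2_qt <- function(n, var_pi = 2e-5) sqrt(var_h2_qt(n, var_pi))

#' @rdname var_h2_qt
#' @export
var_h2_cc_obs <- function(n_case, n_control, var_pi = 2e-5) {
  stopifnot(all(n_case >= 1), all(n_control >= 1))
  var_h2_qt(n_case + n_control, var_pi)
}

#' @rdname var_h2_qt
#' @export
se_h2_cc_obs <- function(n_case, n_control, var_pi = 2e-5) {
  sqrt(var_h2_cc_obs(n_case, n_control, var_pi))
}

#' Standard error of liability-scale SNP heritability in a case-control study
#'
#' The observed-scale standard error [se_h2_cc_obs()] multiplied by the
#' linear observed-to-liability conversion factor `c(K, v)` of the
#' [liability_model()].  Because the transformation is linear, the ratio of
#' the liability- to observed-scale standard errors equals `c` exactly for
#' any design.
#'
#' @inheritParams var_h2_qt
#' @inheritParams liability_model
#' @param v Proportion of cases; defaults to `n_case / (n_case + n_control)`.
#' @return Standard error of the liability-scale heritability estimate.
#' @examples
#' se_h2_cc_liab(1000, 1000, K = 0.01)  # rare disease, balanced ascertainment
#' @export
se_h2_cc_liab <- function(n_case, n_control, K,
                          v = n_case / (n_case + n_control),
                          var_pi = 2e-5) {
  model <- liability_model(K, v)
  se_h2_cc_obs(n_case, n_control, var_pi) * model$c
}

#' Sampling variance of the genetic-correlation estimate
#'
#' Closed-form approximations to the sampling variance of the estimated
#' genetic correlation \eqn{\hat r_G = \hat c /\sqrt{\hat h^2_1 \hat h^2_2}}
#' from a bivariate GREML/HE analysis of two traits.
#'
#' When both traits are measured on the **same** `n` individuals,
#' \deqn{\mathrm{var}(\hat r_G) \approx
#'   \frac{(1 - r_G r_P)^2 + (r_G - r_P)^2}{N^2\,\mathrm{var}(\pi)\,h^2_1 h^2_2},}
#' which reduces to \eqn{1/(N^2 \mathrm{var}(\pi) h^2_1 h^2_2)} for
#' independent traits and, unlike the classical Reeve--Robertson and
#' Koots--Gibson pedigree approximations, tends to 0 (not spuriously) as
#' \eqn{r_G, r_P \to 1}.
#'
#' When the traits are measured on **different** (disjoint) samples of
#' sizes `n1` and `n2`, a second-order Taylor (delta-method) expansion of
#' the ratio with component variances
#' \eqn{\mathrm{var}(\hat c) = 1/(N_1 N_2 \mathrm{var}(\pi))} and
#' \eqn{\mathrm{var}(\hat h^2_k) = 2/(N_k^2 \mathrm{var}(\pi))} gives
#' \deqn{\mathrm{var}(\hat r_G) \approx \frac{1}{\mathrm{var}(\pi)}\left[
#'   \frac{1}{h^2_1 h^2_2 N_1 N_2} + \frac{r_G^2}{2 h^{4}_1 N_1^2}
#'   + \frac{r_G^2}{2 h^{4}_2 N_2^2}\right].}
#' For case-control traits the formulas apply with observed-scale
#' heritabilities; \eqn{\hat r_G} itself is invariant to the (linear)
#' liability transformation.
#'
#' @param n,n1,n2 Sample sizes.
#' @param h2_1,h2_2 SNP heritabilities of the two traits on the analysis
#'   scale (trait scale for quantitative traits, observed scale for
#'   case-control traits); must be positive.
#' @param rg Genetic correlation parameter.
#' @param rp Phenotypic correlation (same-sample only).
#' @param var_pi Variance of off-diagonal SNP-derived relatedness.
#' @return Sampling variance (`var_*`) or standard error (`se_*`) of
#'   \eqn{\hat r_G}.
#' @examples
#' se_rg_same_sample(4000, 0.5, 0.5, rg = 0, rp = 0)       # 0.112
#' se_rg_diff_samples(17012, 11922, 0.40, 0.39, rg = 0.68) # 0.049
#' @export
var_rg_same_sample <- function(n, h2_1, h2_2, rg, rp, var_pi = 2e-5) {
  check_rg_inputs(h2_1, h2_2, rg, var_pi)
  stopifnot(all(abs(rp) <= 1))
  ((1 - rg * rp)^2 + (rg - rp)^2) / (n^2 * var_pi * h2_1 * h2_2)
}

#' @rdname var_rg_same_sample
#' @export
se_rg_same_sample <- function(n, h2_1, h2_2, rg, rp, var_pi = 2e-5) {
  sqrt(var_rg_same_sample(n, h2_1, h2_2, rg, rp, var_pi))
}

#' @rdname var_rg_same_sample
#' @export
var_rg_diff_samples <- function(n1, n2, h2_1, h2_2, rg, var_pi = 2e-5) {
  check_rg_inputs(h2_1, h2_2, rg, var_pi)
  (1 / var_pi) * (1 / (h2_1 * h2_2 * n1 * n2) +
                    rg^2 / (2 * h2_1^2 * n1^2) +
                    rg^2 / (2 * h2_2^2 * n2^2))
}

#' @rdname var_rg_same_sample
#' @export
se_rg_diff_samples <- function(n1, n2, h2_1, h2_2, rg, var_pi = 2e-5) {
  sqrt(var_rg_diff_samples(n1, n2, h2_1, h2_2, rg, var_pi))
}

check_rg_inputs <- function(h2_1, h2_2, rg, var_pi) {
  if (any(h2_1 <= 0) || any(h2_2 <= 0)) {
    stop("heritabilities must be > 0: the genetic-correlation variance ",
         "divides by h2", call. = FALSE)
  }
  if (any(h2_1 < 0.001) || any(h2_2 < 0.001)) {
    warning("heritability < 0.001: approximation unreliable this close to 0")
  }
  stopifnot(all(abs(rg) <= 1), all(var_pi > 0))
}

#' Genetic-correlation variance for two independent case-control studies
#'
#' Convenience wrappers around [var_rg_diff_samples()] for bivariate
#' analyses involving case-control traits on disjoint samples.  Each
#' case-control trait may be specified by its observed-scale heritability
#' directly, or on the liability scale together with its prevalence `K`
#' and case proportion `v`, in which case the observed-scale value is
#' obtained through the [liability_model()] (the two routes are exactly
#' equivalent).
#'
#' @param n1,n2 Total cases + controls of the two studies (or `n_qt` /
#'   `n_cc` for the quantitative-trait / case-control pairing).
#' @param rg Genetic correlation.
#' @param h2_obs_1,h2_obs_2,h2_obs_cc Observed-scale heritabilities.
#' @param h2_liab_1,h2_liab_2,h2_liab_cc Liability-scale alternatives
#'   (require the matching `K`, `v`).
#' @param K1,v1,K2,v2,K,v Prevalence and case proportion per disease.
#' @param h2_qt Heritability of the quantitative trait.
#' @param var_pi Variance of off-diagonal SNP-derived relatedness.
#' @return Sampling variance of \eqn{\hat r_G}.
#' @examples
#' var_rg_cc_cc(19128, 14044, rg = 0.08, h2_obs_1 = 0.42, h2_obs_2 = 0.22)
#' @export
var_rg_cc_cc <- function(n1, n2, rg,
                         h2_obs_1 = NULL, h2_obs_2 = NULL,
                         h2_liab_1 = NULL, K1 = NULL, v1 = NULL,
                         h2_liab_2 = NULL, K2 = NULL, v2 = NULL,
                         var_pi = 2e-5) {
  h1 <- resolve_h2_obs(h2_obs_1, h2_liab_1, K1, v1, "trait 1")
  h2 <- resolve_h2_obs(h2_obs_2, h2_liab_2, K2, v2, "trait 2")
  var_rg_diff_samples(n1, n2, h1, h2, rg, var_pi)
}

#' @rdname var_rg_cc_cc
#' @export
var_rg_qt_cc <- function(n_qt, n_cc, rg, h2_qt,
                         h2_obs_cc = NULL, h2_liab_cc = NULL,
                         K = NULL, v = NULL, var_pi = 2e-5) {
  h_cc <- resolve_h2_obs(h2_obs_cc, h2_liab_cc, K, v, "case-control trait")
  var_rg_diff_samples(n_qt, n_cc, h2_qt, h_cc, rg, var_pi)
}

resolve_h2_obs <- function(h2_obs, h2_liab, K, v, label) {
  if (!is.null(h2_obs)) return(h2_obs)
  if (is.null(h2_liab) || is.null(K) || is.null(v)) {
    stop(sprintf("%s: supply `h2_obs`, or `h2_liab` with `K` and `v`", label),
         call. = FALSE)
  }
  h2_liab_to_obs(h2_liab, liability_model(K, v))
}

#' Same-sample vs different-samples efficiency ratio
#'
#' For independent traits (`rg = rp = 0`), the ratio of the sampling
#' variance of the genetic correlation when both traits are measured on
#' one sample of `n` to that when they are measured on disjoint samples of
#' `n1` and `n2` is simply `n1 * n2 / n^2` — the ratio of the numbers of
#' informative pairwise contrasts.
#'
#' @param n Same-sample size.
#' @param n1,n2 Different-samples sizes.
#' @return `n1 * n2 / n^2`.
#' @examples
#' ratio_same_vs_diff(4000, 1000, 3000)  # 0.1875
#' @export
ratio_same_vs_diff <- function(n, n1, n2) {
  stopifnot(all(n > 0), all(n1 > 0), all(n2 > 0))
  n1 * n2 / n^2
}

#' Standard error of the heritability estimate for a design
#'
#' Dispatches on [qt_design()] / [cc_design()].  For a case-control design
#' `scale` selects the observed 0/1 scale or the liability scale
#' (`"analysis"` means the trait's own scale: observed for case-control,
#' trait scale for quantitative).
#'
#' @param design A [qt_design()] or [cc_design()].
#' @param scale Reporting scale for case-control designs.
#' @return The standard error.
#' @examples
#' se_h2(qt_design(3925))
#' se_h2(cc_design(1604, 1953, K = 0.001), scale = "liability")
#' @export
se_h2 <- function(design, scale = c("analysis", "observed", "liability")) {
  UseMethod("se_h2")
}

#' @export
se_h2.qt_design <- function(design, scale = "analysis") {
  se_h2_qt(design$n, design$var_pi)
}

#' @export
se_h2.cc_design <- function(design,
                            scale = c("analysis", "observed", "liability")) {
  scale <- match.arg(scale)
  se_obs <- se_h2_cc_obs(design$n_case, design$n_control, design$var_pi)
  if (scale == "liability") se_obs * design$model$c else se_obs
}

#' Sampling variance / standard error of the genetic correlation for a design
#'
#' @param design A [bv_design()].
#' @return The sampling variance (`var_rg`) or standard error (`se_rg`).
#' @examples
#' d <- bv_design(qt_design(4000, h2 = 0.5), qt_design(4000, h2 = 0.5),
#'                rg = 0, mode = "same_sample", rp = 0)
#' se_rg(d)
#' @export
var_rg <- function(design) {
  stopifnot(inherits(design, "bv_design"))
  if (design$mode == "same_sample") {
    var_rg_same_sample(design$n, design$h2_1, design$h2_2,
                       design$rg, design$rp, design$var_pi)
  } else {
    var_rg_diff_samples(design$n1, design$n2, design$h2_1, design$h2_2,
                        design$rg, design$var_pi)
  }
}

#' @rdname var_rg
#' @export
se_rg <- function(design) sqrt(var_rg(design))
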