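#' Published GREML case-control study designs
#'
#' Design parameters and reported standard errors from published
#' single-disease GREML analyses of genome-wide SNP data (observed-scale
#' SNP heritability of eight complex diseases), and from published
#' bivariate analyses of five psychiatric disorders (Cross-Disorder
#' Group / PGC data).  These serve as reference inputs for checking the
#' closed-form standard-error approximations against reported values.
#'
#' @return A data frame.  `published_h2_designs()`: one row per disease
#'   with `disease`, `n_case`, `n_control`, `prevalence`, `h2_obs` and the
#'   reported `se_obs`.  `published_rg_designs()`: one row per disease
#'   pair with the two diseases' prevalences, sample sizes and
#'   observed-scale heritabilities, the estimated genetic correlation `rg`
#'   and the reported `se_obs`.
#' @examples
#' predicted_se_h2(published_h2_designs())
#' @export
published_h2_designs <- function() {
  data.frame(
    disease = c("multiple sclerosis", "Alzheimer's disease", "endometriosis",
                "schizophrenia", "bipolar disorder", "MDD", "ASD", "ADHD"),
    n_case = c(1604, 3290, 3154, 9087, 6704, 9041, 3303, 4163),
    n_control = c(1953, 3849, 6981, 12171, 9031, 9381, 3428, 12040),
    prevalence = c(0.001, 0.020, 0.080, 0.010, 0.010, 0.150, 0.010, 0.050),
    h2_obs = c(0.851, 0.364, 0.231, 0.410, 0.441, 0.177, 0.310, 0.253),
    se_obs = c(0.088, 0.049, 0.036, 0.015, 0.021, 0.017, 0.046, 0.020)
  )
}

#' @rdname published_h2_designs
#' @export
published_rg_designs <- function() {
  data.frame(
    disease1 = c("SCZ", "SCZ", "SCZ", "SCZ", "BPD",
                 "BPD", "BPD", "MDD", "MDD", "ASD"),
    K1 = c(0.01, 0.01, 0.01, 0.01, 0.01, 0.01, 0.01, 0.15, 0.15, 0.01),
    n_case1 = c(9032, 9051, 9111, 9013, 6665, 6704, 6656, 9031, 8936, 3156),
    n_control1 = c(7980, 10385, 12146, 10115, 7408, 9030, 7041, 9370, 8668,
                   3254),
    h2_obs1 = c(0.40, 0.38, 0.41, 0.42, 0.42, 0.43, 0.38, 0.17, 0.16, 0.27),
    disease2 = c("BPD", "MDD", "ASD", "ADHD", "MDD",
                 "ASD", "ADHD", "ASD", "ADHD", "ADHD"),
    K2 = c(0.01, 0.15, 0.01, 0.05, 0.15, 0.01, 0.05, 0.01, 0.05, 0.05),
    n_case2 = c(6664, 8998, 3226, 4108, 8997, 3207, 4099, 3239, 4098, 4181),
    n_control2 = c(5258, 7823, 3308, 9936, 7680, 3294, 9873, 3331, 11233,
                   12022),
    h2_obs2 = c(0.39, 0.16, 0.29, 0.22, 0.17, 0.31, 0.25, 0.31, 0.24, 0.23),
    rg = c(0.68, 0.43, 0.16, 0.08, 0.47, 0.04, 0.05, 0.05, 0.32, -0.13),
    se_obs = c(0.044, 0.055, 0.059, 0.046, 0.061, 0.065, 0.053, 0.089,
               0.071, 0.087)
  )
}

#' Predicted standard errors for published study designs
#'
#' Applies the closed-form approximations to a table of published designs:
#' `predicted_se_h2()` adds the predicted observed-scale SE of the
#' SNP-heritability estimate, \eqn{\sqrt{2/(N^2\mathrm{var}(\pi))}} with
#' `N` the total cases + controls; `predicted_se_rg()` adds the predicted
#' SE of the genetic-correlation estimate from the different-samples
#' delta-method formula with the tabulated observed-scale heritabilities
#' and correlation.  `se_approx` holds the full-precision value and
#' `se_approx_3dp` its 3-decimal table form.
#'
#' @param designs A data frame as returned by [published_h2_designs()] /
#'   [published_rg_designs()] (respectively).
#' @param var_pi Variance of off-diagonal SNP-derived relatedness.
#' @return The input data frame with `se_approx` and `se_approx_3dp`
#'   columns appended.
#' @export
predicted_se_h2 <- function(designs = published_h2_designs(),
                            var_pi = 2e-5) {
  designs$se_approx <- se_h2_cc_obs(designs$n_case, designs$n_control, var_pi)
  designs$se_approx_3dp <- round(designs$se_approx, 3)
  designs
}

#' @rdname predicted_se_h2
#' @export
predicted_se_rg <- function(designs = published_rg_designs(),
                            var_pi = 2e-5) {
  designs$se_approx <- se_rg_diff_samples(
    designs$n_case1 + designs$n_control1,
    designs$n_case2 + designs$n_control2,
    designs$h2_obs1, designs$h2_obs2, designs$rg, var_pi)
  designs$se_approx_3dp <- round(designs$se_approx, 3)
  designs
}
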