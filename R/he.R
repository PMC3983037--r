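#' Haseman-Elston regression estimate of SNP heritability
#'
#' Ordinary least-squares regression of the pairwise phenotype product
#' \eqn{Z_{jk} = y_j y_k} on the pairwise SNP-derived relatedness
#' \eqn{A_{jk}} over all \eqn{N(N-1)/2} pairs \eqn{j < k}.  For
#' standardized phenotypes in unrelated samples the slope is an estimate
#' of \eqn{h^2_{SNP}}, asymptotically equivalent to REML, and its sampling
#' variance is approximately \eqn{2/(N^2 \mathrm{var}(\pi))}.  The fit is
#' computed from closed-form sums of moments, which is algebraically
#' identical to materializing every pair.
#'
#' Two standard errors are reported: `se_empirical`, from the regression
#' residual variance, \eqn{\sqrt{\mathrm{var}(e)/(n_{pairs}
#' \mathrm{var}(A))}}, and `se_theory`,
#' \eqn{\sqrt{2/(N^2 \widehat{\mathrm{var}(\pi)})}} with the empirical
#' off-diagonal variance of the supplied GRM.
#'
#' @param y Phenotype vector, one value per GRM individual.
#' @param grm A `grm` object (see [compute_grm()]).
#' @param standardize Standardize `y` to mean 0, variance 1 first
#'   (the variance approximations assume unit phenotypic variance).
#' @return An object of class `he_fit`: list with `slope`, `intercept`,
#'   `se_empirical`, `se_theory`, `n_contrasts`, `var_pi`.
#' @examples
#' g <- simulate_genotypes(300, 1000, seed = 7)
#' tr <- simulate_trait(g, h2 = 0.5, n_causal = 200, seed = 8)
#' he_univariate(tr$y, compute_grm(g))
#' @export
he_univariate <- function(y, grm, standardize = TRUE) {
  stopifnot(inherits(grm, "grm"))
  n <- length(grm$ids)
  if (length(y) != n) stop("`y` length must match the GRM", call. = FALSE)
  if (anyNA(y)) stop("missing phenotypes are not supported here; subset first",
                     call. = FALSE)
  if (stats::sd(y) == 0) stop("phenotype has zero variance", call. = FALSE)
  if (standardize) y <- (y - mean(y)) / stats::sd(y)
  he_fit_from_moments(pair_moments_sym(y, y, grm$A), n = n,
                      theory = "univariate")
}

#' Haseman-Elston regression estimate of genetic covariance (cross-set)
#'
#' OLS of the cross-set phenotype product \eqn{Z_{ij} = y_{1i} y_{2j}} on
#' the cross-set relatedness block \eqn{(A_{12})_{ij}} over all
#' \eqn{N_1 N_2} ordered pairs.  For standardized phenotypes on disjoint
#' samples of unrelated individuals the slope estimates the genetic
#' covariance \eqn{c = r_G\sqrt{h^2_1 h^2_2}} with sampling variance
#' approximately \eqn{1/(N_1 N_2 \mathrm{var}(\pi))}.
#'
#' @param y1,y2 Phenotype vectors for the two (disjoint) sample sets.
#' @param a12 The `N1 x N2` cross-set GRM block (a plain matrix; if it has
#'   dimnames, the two id sets must be disjoint).
#' @param standardize Standardize each phenotype first.
#' @return An `he_fit` object (slope = estimated genetic covariance).
#' @export
he_cross_covariance <- function(y1, y2, a12, standardize = TRUE) {
  a12 <- as.matrix(a12)
  if (length(y1) != nrow(a12) || length(y2) != ncol(a12)) {
    stop("phenotype lengths must match the dimensions of `a12`",
         call. = FALSE)
  }
  if (!is.null(rownames(a12)) && !is.null(colnames(a12)) &&
      length(intersect(rownames(a12), colnames(a12))) > 0) {
    stop("the two sample sets overlap: cross-set regression assumes disjoint ",
         "samples with no residual covariance", call. = FALSE)
  }
  if (stats::sd(y1) == 0 || stats::sd(y2) == 0) {
    stop("phenotype has zero variance", call. = FALSE)
  }
  if (standardize) {
    y1 <- (y1 - mean(y1)) / stats::sd(y1)
    y2 <- (y2 - mean(y2)) / stats::sd(y2)
  }
  n_pairs <- length(y1) * length(y2)
  mom <- list(
    n_pairs = n_pairs,
    sum_z = sum(y1) * sum(y2),
    sum_z2 = sum(y1^2) * sum(y2^2),
    sum_a = sum(a12),
    sum_a2 = sum(a12^2),
    sum_za = drop(crossprod(y1, a12 %*% y2))
  )
  he_fit_from_moments(mom, n = c(length(y1), length(y2)), theory = "cross")
}

#' Bivariate Haseman-Elston analysis: genetic correlation
#'
#' Estimates the genetic correlation
#' \eqn{\hat r_G = \hat c/\sqrt{\hat h^2_1 \hat h^2_2}} by composing HE
#' regressions.  In same-sample mode the genetic covariance is estimated
#' by regressing the symmetrized cross product
#' \eqn{(y_{1j} y_{2k} + y_{1k} y_{2j})/2} on \eqn{A_{jk}} over pairs
#' \eqn{j<k} (the minimum-variance unbiased combination of the two
#' orderings), alongside a univariate fit per trait.  In
#' different-samples mode each trait gets a univariate fit on its own GRM
#' block and the covariance comes from [he_cross_covariance()] on the
#' cross block.  If either heritability estimate is non-positive the
#' correlation is undefined and reported as `NA` with `rg_defined =
#' FALSE`, never clipped.
#'
#' @param y1,y2 Phenotypes.  Same-sample mode: both of length `n` matching
#'   `grm`.  Different-samples mode: `y1` for `set1`, `y2` for `set2`.
#' @param grm A `grm` over all individuals involved.
#' @param mode `"same_sample"` or `"different_samples"`.
#' @param set1,set2 (different-samples mode) disjoint index vectors into
#'   the GRM giving the two sample sets.
#' @param standardize Standardize phenotypes first.
#' @return An object of class `he_bivariate_fit`: `he_fit`s `h2_1`,
#'   `h2_2`, `cov`, plus `rg`, `rg_defined`, `rp` (same-sample only) and
#'   `se_rg_theory` (the closed-form approximation evaluated at the
#'   estimates with the empirical relatedness variance).
#' @export
he_bivariate <- function(y1, y2, grm,
                         mode = c("same_sample", "different_samples"),
                         set1 = NULL, set2 = NULL, standardize = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(grm, "grm"))
  if (mode == "same_sample") {
    n <- length(grm$ids)
    stopifnot(length(y1) == n, length(y2) == n)
    fit1 <- he_univariate(y1, grm, standardize)
    fit2 <- he_univariate(y2, grm, standardize)
    if (standardize) {
      y1s <- (y1 - mean(y1)) / stats::sd(y1)
      y2s <- (y2 - mean(y2)) / stats::sd(y2)
    } else {
      y1s <- y1; y2s <- y2
    }
    cov_fit <- he_fit_from_moments(pair_moments_sym(y1s, y2s, grm$A),
                                   n = n, theory = "cross_same")
    rp <- stats::cor(y1, y2)
    var_pi <- fit1$var_pi
  } else {
    if (is.null(set1) || is.null(set2)) {
      stop("different-samples mode needs `set1` and `set2` indices",
           call. = FALSE)
    }
    if (length(intersect(set1, set2)) > 0) {
      stop("`set1` and `set2` overlap: the two samples must be disjoint",
           call. = FALSE)
    }
    g1 <- subset_grm(grm, set1)
    g2 <- subset_grm(grm, set2)
    fit1 <- he_univariate(y1, g1, standardize)
    fit2 <- he_univariate(y2, g2, standardize)
    cov_fit <- he_cross_covariance(y1, y2, grm$A[set1, set2, drop = FALSE],
                                   standardize)
    rp <- NULL
    var_pi <- cov_fit$var_pi
  }
  h1 <- fit1$slope
  h2 <- fit2$slope
  defined <- h1 > 0 && h2 > 0
  rg <- if (defined) cov_fit$slope / sqrt(h1 * h2) else NA_real_
  se_rg <- if (!defined) {
    NA_real_
  } else if (mode == "same_sample") {
    se_rg_same_sample(length(grm$ids), h1, h2,
                      rg = max(-1, min(1, rg)), rp = rp, var_pi = var_pi)
  } else {
    se_rg_diff_samples(length(set1), length(set2), h1, h2,
                       rg = max(-1, min(1, rg)), var_pi = var_pi)
  }
  structure(list(h2_1 = fit1, h2_2 = fit2, cov = cov_fit,
                 rg = rg, rg_defined = defined, rp = rp,
                 mode = mode, se_rg_theory = se_rg),
            class = "he_bivariate_fit")
}

#' @export
print.he_fit <- function(x, ...) {
  cat(sprintf(
    "HE regression: slope %.4f (SE %.4f empirical, %.4f theory), %d contrasts\n",
    x$slope, x$se_empirical, x$se_theory, x$n_contrasts))
  invisible(x)
}

#' @export
print.he_bivariate_fit <- function(x, ...) {
  cat(sprintf("Bivariate HE analysis (%s)\n", gsub("_", " ", x$mode)))
  cat(sprintf("  h2_1 = %.4f, h2_2 = %.4f, cov = %.4f\n",
              x$h2_1$slope, x$h2_2$slope, x$cov$slope))
  if (x$rg_defined) {
    cat(sprintf("  rg = %.4f (theory SE %.4f)\n", x$rg, x$se_rg_theory))
  } else {
    cat("  rg undefined (non-positive heritability estimate)\n")
  }
  invisible(x)
}

# sums over pairs j<k of z = (u_j v_k + u_k v_j)/2 against A_jk, computed
# from O(n^2) matrix moments rather than by expanding the pairs
pair_moments_sym <- function(u, v, A) {
  n <- length(u)
  d <- diag(A)
  uv <- u * v
  sum_a <- (sum(A) - sum(d)) / 2
  sum_a2 <- (sum(A^2) - sum(d^2)) / 2
  sum_z <- (sum(u) * sum(v) - sum(uv)) / 2
  sum_za <- (drop(crossprod(u, A %*% v)) - sum(d * uv)) / 2
  sum_z2 <- (sum(u^2) * sum(v^2) - sum(u^2 * v^2) +
               sum(uv)^2 - sum(uv^2)) / 4
  list(n_pairs = n * (n - 1) / 2, sum_z = sum_z, sum_z2 = sum_z2,
       sum_a = sum_a, sum_a2 = sum_a2, sum_za = sum_za)
}

he_fit_from_moments <- function(mom, n, theory) {
  np <- mom$n_pairs
  s_aa <- mom$sum_a2 - mom$sum_a^2 / np
  if (s_aa <= 0) stop("no variance in pairwise relatedness", call. = FALSE)
  s_za <- mom$sum_za - mom$sum_z * mom$sum_a / np
  s_zz <- mom$sum_z2 - mom$sum_z^2 / np
  slope <- s_za / s_aa
  intercept <- (mom$sum_z - slope * mom$sum_a) / np
  sse <- s_zz - slope * s_za
  se_emp <- sqrt(max(sse, 0) / (np * s_aa))
  var_pi <- s_aa / (np - 1)
  se_theory <- switch(theory,
    univariate = sqrt(2 / (n^2 * var_pi)),
    cross = sqrt(1 / (n[1] * n[2] * var_pi)),
    cross_same = sqrt(1 / (n^2 * var_pi))
  )
  structure(list(slope = slope, intercept = intercept,
                 se_empirical = se_emp, se_theory = se_theory,
                 n_contrasts = np, var_pi = var_pi),
            class = "he_fit")
}

# restrict a GRM to a subset of individuals
subset_grm <- function(grm, idx) {
  structure(list(ids = grm$ids[idx],
                 A = grm$A[idx, idx, drop = FALSE],
                 n_snps = grm$n_snps[idx, idx, drop = FALSE],
                 m = grm$m, n_dropped = grm$n_dropped),
            class = "grm")
}
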