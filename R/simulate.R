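#' Simulate unlinked SNP genotypes in Hardy-Weinberg equilibrium
#'
#' Draws per-SNP allele frequencies uniformly from `maf_range` and
#' genotypes independently as Binomial(2, p) per individual: unrelated
#' individuals, Hardy-Weinberg and linkage equilibrium.  For such
#' independent loci the variance of off-diagonal SNP-derived relatedness
#' is `1/m`, which plays the role that `2e-5` plays for genome-wide common
#' SNPs in real human data, so the verification harness is self-contained
#' at desk scale.
#'
#' @param n Number of individuals.
#' @param m Number of SNPs.
#' @param maf_range Interval within (0, 0.5] for allele frequencies.
#' @param freqs Optional fixed frequency vector (overrides `maf_range`).
#' @param seed Optional integer seed; a given seed reproduces the matrix
#'   bit-identically.
#' @return A [genotype_matrix()].
#' @examples
#' g <- simulate_genotypes(100, 200, seed = 1)
#' @export
simulate_genotypes <- function(n, m, maf_range = c(0.05, 0.5),
                               freqs = NULL, seed = NULL) {
  check_count(n, "n", min = 2)
  check_count(m, "m", min = 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(freqs)) {
    stopifnot(length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
              maf_range[1] <= maf_range[2])
    freqs <- stats::runif(m, maf_range[1], maf_range[2])
  }
  counts <- matrix(stats::rbinom(n * m, 2, rep(freqs, each = n)), n, m)
  genotype_matrix(counts, ids = sprintf("id%d", seq_len(n)))
}

#' Simulate a polygenic quantitative trait
#'
#' Additive polygenic architecture: `n_causal` SNPs are chosen at random,
#' effects are drawn standard normal on the standardized genotype scale,
#' genetic values are rescaled so that their realized variance is exactly
#' `h2`, and residuals are drawn normal with variance `1 - h2`
#' (`y = g + e`).
#'
#' @param geno A [genotype_matrix()].
#' @param h2 SNP heritability in `[0, 1]`.
#' @param n_causal Number of causal SNPs (`<= m`); default
#'   `min(m, 1000)`.
#' @param seed Optional integer seed.
#' @return List with `y` (phenotype), `g` (true genetic values), `causal`
#'   (causal SNP indices) and `effects`.
#' @export
simulate_trait <- function(geno, h2, n_causal = NULL, seed = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  check_h2_range(h2, "h2")
  m <- ncol(geno$counts)
  if (is.null(n_causal)) n_causal <- min(m, 1000L)
  check_count(n_causal, "n_causal", min = 1)
  if (n_causal > m) stop("`n_causal` must not exceed the number of SNPs",
                         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(geno$counts)
  causal <- sort(sample.int(m, n_causal))
  b <- stats::rnorm(n_causal)
  g <- scaled_genetic_values(geno, causal, b, h2)
  e <- if (h2 < 1) stats::rnorm(n, sd = sqrt(1 - h2)) else numeric(n)
  list(y = g + e, g = g, causal = causal, effects = b)
}

#' Simulate a genetically correlated pair of polygenic traits
#'
#' Two traits with heritabilities `h2_1`, `h2_2` and genetic correlation
#' `rg`, induced by one of two mechanisms:
#' * `"shared_fraction"` — each trait has `n_causal` causal SNPs of which
#'   a fraction `rg` are shared with identical effects (the remaining
#'   causal SNPs are trait-specific with independent effects), so the
#'   genetic correlation equals the shared fraction.  Requires
#'   `0 <= rg <= 1` and enough SNPs for the two partially overlapping
#'   causal sets.
#' * `"correlated_effects"` — one shared causal set whose per-SNP effect
#'   pairs are drawn from a bivariate normal with correlation `rg`.
#'
#' Genetic values are rescaled to realized variance `h2_k`; residual
#' pairs are drawn with correlation `re` (relevant when the traits are
#' measured on the same individuals), so that the phenotypic correlation
#' is \eqn{r_P = r_G\sqrt{h^2_1 h^2_2} + r_e\sqrt{(1-h^2_1)(1-h^2_2)}}.
#' All individuals receive both traits; for a different-samples analysis
#' take `y1` on one subset and `y2` on a disjoint subset.
#'
#' @inheritParams simulate_trait
#' @param h2_1,h2_2 Heritabilities of the two traits.
#' @param rg Target genetic correlation.
#' @param mechanism `"shared_fraction"` or `"correlated_effects"`.
#' @param re Residual correlation, in `[-1, 1]`.
#' @return List with `y1`, `y2`, `g1`, `g2` and the causal sets/effects.
#' @export
simulate_trait_pair <- function(geno, h2_1, h2_2, rg,
                                mechanism = c("shared_fraction",
                                              "correlated_effects"),
                                re = 0, n_causal = NULL, seed = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  mechanism <- match.arg(mechanism)
  check_h2_range(h2_1, "h2_1")
  check_h2_range(h2_2, "h2_2")
  stopifnot(abs(rg) <= 1, abs(re) <= 1)
  m <- ncol(geno$counts)
  n <- nrow(geno$counts)
  if (is.null(n_causal)) n_causal <- min(m, 1000L)
  check_count(n_causal, "n_causal", min = 1)
  if (!is.null(seed)) set.seed(seed)
  if (mechanism == "shared_fraction") {
    if (rg < 0) {
      stop("shared_fraction cannot induce a negative genetic correlation; ",
           "use mechanism = \"correlated_effects\"", call. = FALSE)
    }
    n_shared <- round(rg * n_causal)
    n_needed <- 2 * n_causal - n_shared
    if (n_needed > m) {
      stop(sprintf(paste0(
        "shared_fraction needs %d SNPs for two causal sets sharing %d; ",
        "only %d available. Reduce n_causal or use correlated_effects"),
        n_needed, n_shared, m), call. = FALSE)
    }
    loci <- sample.int(m, n_needed)
    shared <- loci[seq_len(n_shared)]
    own1 <- loci[n_shared + seq_len(n_causal - n_shared)]
    own2 <- loci[n_causal + seq_len(n_causal - n_shared)]
    causal1 <- c(shared, own1)
    causal2 <- c(shared, own2)
    b_shared <- stats::rnorm(n_shared)
    b1 <- c(b_shared, stats::rnorm(n_causal - n_shared))
    b2 <- c(b_shared, stats::rnorm(n_causal - n_shared))
  } else {
    causal1 <- causal2 <- sort(sample.int(m, n_causal))
    z1 <- stats::rnorm(n_causal)
    z2 <- stats::rnorm(n_causal)
    b1 <- z1
    b2 <- rg * z1 + sqrt(1 - rg^2) * z2
  }
  g1 <- scaled_genetic_values(geno, causal1, b1, h2_1)
  g2 <- scaled_genetic_values(geno, causal2, b2, h2_2)
  u1 <- stats::rnorm(n)
  u2 <- re * u1 + sqrt(1 - re^2) * stats::rnorm(n)
  e1 <- sqrt(1 - h2_1) * u1
  e2 <- sqrt(1 - h2_2) * u2
  list(y1 = g1 + e1, y2 = g2 + e2, g1 = g1, g2 = g2,
       causal1 = causal1, causal2 = causal2, effects1 = b1, effects2 = b2)
}

# genetic values from standardized causal genotypes, rescaled so the
# realized variance is exactly h2
scaled_genetic_values <- function(geno, causal, b, h2) {
  n <- nrow(geno$counts)
  if (h2 == 0) return(numeric(n))
  x <- geno$counts[, causal, drop = FALSE]
  p <- geno$freqs[causal]
  w <- sweep(x, 2, 2 * p, "-")
  w <- sweep(w, 2, sqrt(2 * p * (1 - p)), "/")
  g <- drop(w %*% b)
  s <- stats::sd(g)
  if (s == 0) stop("degenerate genetic values (zero variance)", call. = FALSE)
  g * sqrt(h2) / s
}

#' Simulate an ascertained case-control study under the liability model
#'
#' Simulates a population pool of genotypes, assigns each individual a
#' liability `g + e` with realized genetic variance `h2_liab`, declares
#' individuals with liability above `qnorm(1 - K)` affected, and samples
#' `n_case` cases and `n_control` controls without replacement.  The pool
#' is `pool_mult` times the target sample size (default
#' `max(5, ceiling(2 * v / K))`, enough to supply the cases of a rare
#' disease with a margin).
#'
#' @param n_case,n_control Target case and control counts.
#' @param K Disease prevalence.
#' @param h2_liab Liability-scale SNP heritability.
#' @param m Number of SNPs.
#' @param maf_range,n_causal As in [simulate_genotypes()] /
#'   [simulate_trait()].
#' @param pool_mult Pool size multiplier.
#' @param seed Optional integer seed.
#' @return List with `geno` (the selected individuals' genotypes, allele
#'   frequencies re-estimated in the ascertained sample), `status`
#'   (0/1 phenotype), `g` (true genetic values of the selected), `model`
#'   (the [liability_model()] at the realized case proportion), and
#'   `pool_n`.
#' @export
simulate_case_control <- function(n_case, n_control, K, h2_liab,
                                  m = 1000, maf_range = c(0.05, 0.5),
                                  n_causal = NULL, pool_mult = NULL,
                                  seed = NULL) {
  check_count(n_case, "n_case")
  check_count(n_control, "n_control")
  check_probability(K, "K", tol = 1e-6)
  check_h2_range(h2_liab, "h2_liab")
  if (!is.null(seed)) set.seed(seed)
  n_target <- n_case + n_control
  v <- n_case / n_target
  if (is.null(pool_mult)) pool_mult <- max(5, ceiling(2 * v / K))
  pool_n <- ceiling(pool_mult * n_target)
  pool <- simulate_genotypes(pool_n, m, maf_range)
  tr <- simulate_trait(pool, h2 = h2_liab, n_causal = n_causal)
  affected <- tr$y > stats::qnorm(1 - K)
  if (sum(affected) < n_case) {
    stop(sprintf(
      "pool of %d yielded only %d cases (need %d); raise pool_mult",
      pool_n, sum(affected), n_case), call. = FALSE)
  }
  if (sum(!affected) < n_control) {
    stop(sprintf(
      "pool of %d yielded only %d controls (need %d); raise pool_mult",
      pool_n, sum(!affected), n_control), call. = FALSE)
  }
  sel <- c(sample(which(affected), n_case),
           sample(which(!affected), n_control))
  status <- c(rep(1L, n_case), rep(0L, n_control))
  geno <- genotype_matrix(pool$counts[sel, , drop = FALSE],
                          ids = pool$ids[sel])
  list(geno = geno, status = status, g = tr$g[sel],
       model = liability_model(K, v), pool_n = pool_n)
}

#' Replicate harness verifying the sampling-variance approximations
#'
#' Runs `n_replicates` simulation + Haseman-Elston estimation cycles for a
#' chosen design and compares the spread of the estimates with the
#' closed-form predictions.  Mirroring the design of simulation studies on
#' a fixed genotype panel, the genotypes (and hence the GRM) are simulated
#' once per run and the causal effects and residuals are redrawn each
#' replicate; set `new_genotypes = TRUE` to regenerate genotypes per
#' replicate.  Theory standard errors are reported both with the
#' reference relatedness variance for independent loci (`1/m`) and with
#' the empirical off-diagonal variance of the simulated GRM.
#'
#' All randomness flows from `seed`: per-replicate sub-seeds are drawn up
#' front, so replicate `r` is reproducible independently of the others.
#'
#' @param mode One of `"univariate"`, `"bivariate_same"`,
#'   `"bivariate_diff"`, `"case_control"`.
#' @param n Sample size per trait (`"bivariate_diff"` uses `n1`, `n2`).
#' @param n1,n2 Sample sizes of the two disjoint sets
#'   (`"bivariate_diff"`).
#' @param m Number of simulated SNPs.
#' @param n_causal Causal SNPs per trait.
#' @param h2,h2_1,h2_2 Heritabilities (liability-scale in
#'   `"case_control"` mode).
#' @param rg,mechanism,re Bivariate parameters, see
#'   [simulate_trait_pair()].
#' @param K,v Case-control parameters (`v` defaults to 0.5).
#' @param maf_range,pool_mult Passed to the simulators.
#' @param n_replicates Number of replicates.
#' @param seed Integer seed.
#' @param new_genotypes Regenerate genotypes every replicate.
#' @return An object of class `greml_verification`: list with `mode`,
#'   `config`, `replicates` (one row per replicate: estimate and
#'   empirical SE) and `summary` (mean estimate, SD across replicates,
#'   mean empirical SE, theory SEs, empirical relatedness variance).
#' @examples
#' \donttest{
#' v <- run_replicates("univariate", n = 500, m = 2000, n_causal = 500,
#'                     h2 = 0.5, n_replicates = 20, seed = 1)
#' v
#' }
#' @export
run_replicates <- function(mode = c("univariate", "bivariate_same",
                                    "bivariate_diff", "case_control"),
                           n = 2000, n1 = n, n2 = n, m = 10000,
                           n_causal = 1000, h2 = 0.5, h2_1 = h2, h2_2 = h2,
                           rg = 0, mechanism = "shared_fraction", re = 0,
                           K = NULL, v = 0.5, maf_range = c(0.05, 0.5),
                           pool_mult = NULL, n_replicates = 100, seed = 1,
                           new_genotypes = FALSE) {
  mode <- match.arg(mode)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, n_replicates + 1)
  config <- list(mode = mode, n = n, n1 = n1, n2 = n2, m = m,
                 n_causal = n_causal, h2 = h2, h2_1 = h2_1, h2_2 = h2_2,
                 rg = rg, mechanism = mechanism, re = re, K = K, v = v,
                 n_replicates = n_replicates, seed = seed,
                 new_genotypes = new_genotypes)

  rows <- vector("list", n_replicates)

  if (mode == "univariate") {
    geno <- simulate_genotypes(n, m, maf_range, seed = seeds[1])
    grm <- compute_grm(geno)
    for (r in seq_len(n_replicates)) {
      if (new_genotypes) {
        geno <- simulate_genotypes(n, m, maf_range, seed = seeds[r + 1])
        grm <- compute_grm(geno)
      }
      tr <- simulate_trait(geno, h2 = h2, n_causal = n_causal,
                           seed = seeds[r + 1])
      fit <- he_univariate(tr$y, grm)
      rows[[r]] <- data.frame(replicate = r, estimate = fit$slope,
                              se_empirical = fit$se_empirical)
    }
    var_pi_emp <- empirical_var_pi(grm, relatedness_cutoff = NULL)
    theory_emp <- sqrt(2 / (n^2 * var_pi_emp))
    theory_ref <- sqrt(2 / (n^2 * (1 / m)))
    truth <- h2
  } else if (mode == "bivariate_same") {
    geno <- simulate_genotypes(n, m, maf_range, seed = seeds[1])
    grm <- compute_grm(geno)
    for (r in seq_len(n_replicates)) {
      if (new_genotypes) {
        geno <- simulate_genotypes(n, m, maf_range, seed = seeds[r + 1])
        grm <- compute_grm(geno)
      }
      pair <- simulate_trait_pair(geno, h2_1, h2_2, rg, mechanism, re,
                                  n_causal, seed = seeds[r + 1])
      fit <- he_bivariate(pair$y1, pair$y2, grm, mode = "same_sample")
      rows[[r]] <- data.frame(replicate = r, estimate = fit$rg,
                              se_empirical = fit$se_rg_theory)
    }
    var_pi_emp <- empirical_var_pi(grm, relatedness_cutoff = NULL)
    rp <- rg * sqrt(h2_1 * h2_2) + re * sqrt((1 - h2_1) * (1 - h2_2))
    theory_emp <- se_rg_same_sample(n, h2_1, h2_2, rg, rp, var_pi_emp)
    theory_ref <- se_rg_same_sample(n, h2_1, h2_2, rg, rp, 1 / m)
    truth <- rg
  } else if (mode == "bivariate_diff") {
    n_all <- n1 + n2
    set1 <- seq_len(n1)
    set2 <- n1 + seq_len(n2)
    geno <- simulate_genotypes(n_all, m, maf_range, seed = seeds[1])
    grm <- compute_grm(geno)
    for (r in seq_len(n_replicates)) {
      if (new_genotypes) {
        geno <- simulate_genotypes(n_all, m, maf_range, seed = seeds[r + 1])
        grm <- compute_grm(geno)
      }
      pair <- simulate_trait_pair(geno, h2_1, h2_2, rg, mechanism, re = 0,
                                  n_causal, seed = seeds[r + 1])
      fit <- he_bivariate(pair$y1[set1], pair$y2[set2], grm,
                          mode = "different_samples",
                          set1 = set1, set2 = set2)
      rows[[r]] <- data.frame(replicate = r, estimate = fit$rg,
                              se_empirical = fit$se_rg_theory)
    }
    var_pi_emp <- empirical_var_pi(grm, relatedness_cutoff = NULL)
    theory_emp <- se_rg_diff_samples(n1, n2, h2_1, h2_2, rg, var_pi_emp)
    theory_ref <- se_rg_diff_samples(n1, n2, h2_1, h2_2, rg, 1 / m)
    truth <- rg
  } else { # case_control
    if (is.null(K)) stop("case_control mode needs `K`", call. = FALSE)
    n_case <- round(v * n)
    n_control <- n - n_case
    model <- liability_model(K, v)
    var_pis <- numeric(n_replicates)
    for (r in seq_len(n_replicates)) {
      cc <- simulate_case_control(n_case, n_control, K, h2_liab = h2,
                                  m = m, maf_range = maf_range,
                                  n_causal = n_causal,
                                  pool_mult = pool_mult,
                                  seed = seeds[r + 1])
      grm_cc <- compute_grm(cc$geno)
      fit <- he_univariate(cc$status, grm_cc)
      var_pis[r] <- empirical_var_pi(grm_cc, relatedness_cutoff = NULL)
      rows[[r]] <- data.frame(replicate = r,
                              estimate = fit$slope * model$c,
                              se_empirical = fit$se_empirical * model$c)
    }
    var_pi_emp <- mean(var_pis)
    theory_emp <- sqrt(2 / (n^2 * var_pi_emp)) * model$c
    theory_ref <- sqrt(2 / (n^2 * (1 / m))) * model$c
    truth <- h2
  }

  reps <- do.call(rbind, rows)
  est <- reps$estimate
  summary <- list(
    truth = truth,
    mean_estimate = mean(est),
    sd_estimate = stats::sd(est),
    sem = stats::sd(est) / sqrt(length(est)),
    mean_se_empirical = mean(reps$se_empirical),
    se_theory_empirical_varpi = theory_emp,
    se_theory_reference_varpi = theory_ref,
    var_pi_empirical = var_pi_emp
  )
  structure(list(mode = mode, config = config, replicates = reps,
                 summary = summary),
            class = "greml_verification")
}

#' @export
print.greml_verification <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Verification run: %s, %d replicates (seed %d)\n",
              x$mode, x$config$n_replicates, x$config$seed))
  cat(sprintf("  truth              : %.4f\n", s$truth))
  cat(sprintf("  mean estimate      : %.4f (SEM %.4f)\n",
              s$mean_estimate, s$sem))
  cat(sprintf("  SD of estimates    : %.4f\n", s$sd_estimate))
  cat(sprintf("  mean empirical SE  : %.4f\n", s$mean_se_empirical))
  cat(sprintf("  theory SE (emp var): %.4f   (1/m var): %.4f\n",
              s$se_theory_empirical_varpi, s$se_theory_reference_varpi))
  cat(sprintf("  empirical var_pi   : %.3e\n", s$var_pi_empirical))
  invisible(x)
}

#' Write a verification report to disk
#'
#' Writes the per-replicate table as CSV (`<prefix>_replicates.csv`) and a
#' human-readable summary (`<prefix>_summary.txt`).
#'
#' @param x A `greml_verification` object.
#' @param prefix Output path prefix.
#' @return The prefix, invisibly.
#' @export
write_verification <- function(x, prefix) {
  stopifnot(inherits(x, "greml_verification"))
  utils::write.csv(x$replicates, paste0(prefix, "_replicates.csv"),
                   row.names = FALSE)
  con <- file(paste0(prefix, "_summary.txt"), "w")
  sink(con)
  on.exit({ sink(); close(con) }, add = TRUE)
  print(x)
  invisible(prefix)
}
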