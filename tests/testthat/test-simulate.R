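test_that("genotype simulation is seed-reproducible and HWE-calibrated", {
  g1 <- simulate_genotypes(100, 200, seed = 61)
  g2 <- simulate_genotypes(100, 200, seed = 61)
  expect_identical(g1$counts, g2$counts)
  expect_identical(g1$freqs, g2$freqs)
  expect_false(identical(g1$counts, simulate_genotypes(100, 200,
                                                       seed = 62)$counts))
  # sample frequency tracks the generating frequency at large n
  set.seed(63)
  p <- runif(50, 0.05, 0.5)
  g <- simulate_genotypes(5000, 50, freqs = p)
  phat <- colMeans(g$counts) / 2
  se_bin <- sqrt(p * (1 - p) / (2 * 5000))
  expect_true(all(abs(phat - p) < 4 * se_bin))
})

test_that("trait simulation hits the target variance decomposition", {
  g <- simulate_genotypes(400, 800, seed = 64)
  tr <- simulate_trait(g, h2 = 0.3, n_causal = 300, seed = 65)
  expect_equal(sd(tr$g), sqrt(0.3), tolerance = 1e-12)
  expect_equal(var(tr$y), 1, tolerance = 0.2)
  # edge cases: h2 = 0 is pure noise, h2 = 1 is pure signal
  tr0 <- simulate_trait(g, h2 = 0, seed = 66)
  expect_true(all(tr0$g == 0))
  tr1 <- simulate_trait(g, h2 = 1, seed = 67)
  expect_equal(tr1$y, tr1$g)
  expect_error(simulate_trait(g, h2 = 0.5, n_causal = 10000), "n_causal")
})

test_that("correlated_effects pairs realize the target genetic correlation", {
  g <- simulate_genotypes(500, 1000, seed = 68)
  cors <- vapply(1:30, function(r) {
    p <- simulate_trait_pair(g, 0.5, 0.5, rg = 0.4,
                             mechanism = "correlated_effects",
                             n_causal = 500, seed = 200 + r)
    cor(p$g1, p$g2)
  }, 0)
  expect_equal(mean(cors), 0.4, tolerance = 3 * sd(cors) / sqrt(30) + 0.02)
})

test_that("shared_fraction realizes rg as the shared-causal proportion", {
  g <- simulate_genotypes(500, 2000, seed = 69)
  cors <- vapply(1:30, function(r) {
    p <- simulate_trait_pair(g, 0.5, 0.5, rg = 0.8,
                             mechanism = "shared_fraction",
                             n_causal = 500, seed = 300 + r)
    cor(p$g1, p$g2)
  }, 0)
  expect_equal(mean(cors), 0.8, tolerance = 3 * sd(cors) / sqrt(30) + 0.02)
  expect_error(simulate_trait_pair(g, 0.5, 0.5, rg = -0.3,
                                   mechanism = "shared_fraction"),
               "correlated_effects")
  expect_error(simulate_trait_pair(g, 0.5, 0.5, rg = 0.1,
                                   mechanism = "shared_fraction",
                                   n_causal = 1500), "n_causal|SNPs")
})

test_that("residual correlation composes into the phenotypic correlation", {
  g <- simulate_genotypes(2000, 500, seed = 70)
  rps <- vapply(1:20, function(r) {
    p <- simulate_trait_pair(g, 0.5, 0.5, rg = 0.4,
                             mechanism = "correlated_effects", re = 0.3,
                             n_causal = 250, seed = 400 + r)
    cor(p$y1, p$y2)
  }, 0)
  rp_expect <- 0.4 * 0.5 + 0.3 * 0.5  # rg*sqrt(h1 h2) + re*sqrt((1-h1)(1-h2))
  expect_equal(mean(rps), rp_expect, tolerance = 3 * sd(rps) / sqrt(20) + 0.02)
})

test_that("case-control ascertainment follows the liability threshold", {
  cc <- simulate_case_control(150, 150, K = 0.1, h2_liab = 0.5, m = 400,
                              n_causal = 200, seed = 71)
  expect_equal(sum(cc$status), 150)
  expect_equal(nrow(cc$geno$counts), 300)
  # cases carry higher genetic values than controls
  expect_gt(mean(cc$g[cc$status == 1]), mean(cc$g[cc$status == 0]))
  # at K = 0.5 without oversampling the pool is roughly half affected
  cc2 <- simulate_case_control(100, 100, K = 0.5, h2_liab = 0.3, m = 200,
                               pool_mult = 5, seed = 72)
  expect_equal(cc2$pool_n, 1000)
  # demanding more cases than a small pool can yield errors informatively
  expect_error(simulate_case_control(500, 100, K = 0.01, h2_liab = 0.3,
                                     m = 100, pool_mult = 2, seed = 73),
               "cases")
})

test_that("liability transform recovers h2 from ascertained 0/1 phenotypes", {
  # end-to-end: HE slope on the observed scale times c(K, v) is unbiased
  # for the liability-scale heritability
  v <- run_replicates("case_control", n = 300, m = 1000, n_causal = 300,
                      h2 = 0.5, K = 0.1, v = 0.5, n_replicates = 30,
                      seed = 74)
  s <- v$summary
  expect_lt(abs(s$mean_estimate - 0.5), 3 * s$sem)
  # and the spread tracks the transformed theory SE
  expect_gt(s$sd_estimate / s$se_theory_empirical_varpi, 0.6)
  expect_lt(s$sd_estimate / s$se_theory_empirical_varpi, 1.6)
})

test_that("replicate harness is reproducible and reports coherent summaries", {
  v1 <- run_replicates("univariate", n = 200, m = 500, n_causal = 200,
                       h2 = 0.5, n_replicates = 5, seed = 75)
  v2 <- run_replicates("univariate", n = 200, m = 500, n_causal = 200,
                       h2 = 0.5, n_replicates = 5, seed = 75)
  expect_identical(v1$replicates, v2$replicates)
  expect_equal(v1$summary$mean_estimate, mean(v1$replicates$estimate))
  # theory SE with the 1/m reference equals the closed form
  expect_equal(v1$summary$se_theory_reference_varpi,
               se_h2_qt(200, var_pi = 1 / 500))
  # report files are written
  pre <- file.path(tempdir(), "verif")
  write_verification(v1, pre)
  expect_true(file.exists(paste0(pre, "_replicates.csv")))
  expect_true(file.exists(paste0(pre, "_summary.txt")))
})
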