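test_that("univariate SE depends only on sample size and matches reports", {
  expect_equal(round(se_h2_qt(3925), 3), 0.081)
  expect_equal(round(se_h2_qt(11586), 3), 0.027)
  # SE is inversely proportional to N and independent of h2 by construction
  expect_equal(se_h2_qt(8000), se_h2_qt(4000) / 2)
  d1 <- qt_design(5000, h2 = 0.1)
  d2 <- qt_design(5000, h2 = 0.9)
  expect_equal(se_h2(d1), se_h2(d2))
  # scales as 1/sqrt(var_pi)
  expect_equal(se_h2_qt(5000, var_pi = 8e-5), se_h2_qt(5000, 2e-5) / 2)
})

test_that("case-control observed-scale SE uses the total sample size only", {
  expect_equal(round(se_h2_cc_obs(1604, 1953), 3), 0.089)
  expect_equal(round(se_h2_cc_obs(9087, 12171), 3), 0.015)
  expect_equal(se_h2_cc_obs(1604, 1953), se_h2_cc_obs(1953, 1604))
  expect_equal(se_h2_cc_obs(2000, 1557), se_h2_qt(3557))
})

test_that("liability-scale SE is the observed-scale SE times c, exactly", {
  expect_equal(se_h2_cc_liab(1779, 1778, K = 0.5, v = 0.5),
               (pi / 2) * se_h2_cc_obs(1779, 1778), tolerance = 1e-12)
  for (K in c(0.01, 0.1, 0.3)) {
    for (v in c(0.3, 0.5)) {
      m <- liability_model(K, v)
      expect_equal(
        se_h2_cc_liab(4000, 6000, K, v) / se_h2_cc_obs(4000, 6000), m$c)
    }
  }
})

test_that("same-sample rG variance has the stated limits", {
  # independent traits: 1/(N^2 var_pi h1 h2)
  expect_equal(var_rg_same_sample(4000, 0.5, 0.5, rg = 0, rp = 0),
               1 / (4000^2 * 2e-5 * 0.25))
  expect_equal(round(se_rg_same_sample(4000, 0.5, 0.5, 0, 0), 4), 0.1118)
  # perfect correlation: variance vanishes continuously
  expect_equal(var_rg_same_sample(4000, 0.5, 0.5, rg = 1, rp = 1), 0)
  eps <- 1e-4
  expect_lt(var_rg_same_sample(4000, 0.5, 0.5, 1 - eps, 1 - eps),
            1e-6 * var_rg_same_sample(4000, 0.5, 0.5, 0, 0))
})

test_that("different-samples rG variance reproduces the reported values", {
  expect_equal(round(se_rg_diff_samples(17012, 11922, 0.40, 0.39, 0.68), 3),
               0.049)
  expect_equal(round(se_rg_diff_samples(19436, 16821, 0.38, 0.16, 0.43), 3),
               0.057)
  # rg = 0 limit, symmetric under trait swap
  expect_equal(var_rg_diff_samples(1000, 3000, 0.5, 0.4, 0),
               1 / (0.5 * 0.4 * 1000 * 3000 * 2e-5))
  expect_equal(var_rg_diff_samples(1000, 3000, 0.5, 0.4, 0),
               var_rg_diff_samples(3000, 1000, 0.4, 0.5, 0))
  # worked value: rg=0, N1=4000, N2=6000, h2=0.5 both
  expect_equal(var_rg_diff_samples(4000, 6000, 0.5, 0.5, 0),
               1 / (0.25 * 2.4e7 * 2e-5))
  expect_equal(round(se_rg_diff_samples(4000, 6000, 0.5, 0.5, 0), 4), 0.0913)
})

test_that("different-samples variance is monotone and bounded below by rg=0", {
  base <- var_rg_diff_samples(4000, 5000, 0.4, 0.3, 0)
  for (rg in c(0.1, 0.4, 0.8, 1, -0.5)) {
    expect_gte(var_rg_diff_samples(4000, 5000, 0.4, 0.3, rg), base)
  }
  v0 <- var_rg_diff_samples(4000, 5000, 0.4, 0.3, 0.5)
  expect_lt(var_rg_diff_samples(8000, 5000, 0.4, 0.3, 0.5), v0)
  expect_lt(var_rg_diff_samples(4000, 9000, 0.4, 0.3, 0.5), v0)
  expect_lt(var_rg_diff_samples(4000, 5000, 0.6, 0.3, 0.5), v0)
  expect_lt(var_rg_diff_samples(4000, 5000, 0.4, 0.5, 0.5), v0)
})

test_that("case-control wrappers delegate and convert scales consistently", {
  # liability-scale input equals pre-converted observed-scale input
  m1 <- liability_model(0.01, 9032 / 17012)
  h2o1 <- h2_liab_to_obs(0.23, m1)
  expect_equal(
    var_rg_cc_cc(17012, 14044, rg = 0.3, h2_obs_1 = h2o1, h2_obs_2 = 0.22),
    var_rg_cc_cc(17012, 14044, rg = 0.3,
                 h2_liab_1 = 0.23, K1 = 0.01, v1 = 9032 / 17012,
                 h2_obs_2 = 0.22))
  # qt-cc pairing equals cc-cc at identical parameters
  expect_equal(var_rg_qt_cc(5000, 6000, rg = 0.4, h2_qt = 0.3,
                            h2_obs_cc = 0.3),
               var_rg_cc_cc(5000, 6000, rg = 0.4, h2_obs_1 = 0.3,
                            h2_obs_2 = 0.3))
  expect_error(var_rg_cc_cc(100, 100, rg = 0, h2_liab_1 = 0.2),
               "K")
})

test_that("same- vs different-sample efficiency ratio is n1*n2/n^2", {
  expect_equal(ratio_same_vs_diff(4000, 4000, 4000), 1)
  expect_equal(ratio_same_vs_diff(4000, 1000, 3000), 0.1875)
  # consistency with the two variance formulas at rg = rp = 0, equal h2
  r <- var_rg_same_sample(4000, 0.5, 0.5, 0, 0) /
    var_rg_diff_samples(1000, 3000, 0.5, 0.5, 0)
  expect_equal(r, ratio_same_vs_diff(4000, 1000, 3000))
})

test_that("degenerate heritabilities are rejected for rG variances", {
  expect_error(var_rg_diff_samples(1000, 1000, 0, 0.5, 0.2), "h2")
  expect_error(var_rg_same_sample(1000, 0.5, 0, 0.2, 0), "h2")
  expect_warning(var_rg_diff_samples(1000, 1000, 5e-4, 0.5, 0.2), "0.001")
})

test_that("design objects validate their bivariate contracts", {
  t1 <- qt_design(4000, h2 = 0.5)
  t2 <- qt_design(4000, h2 = 0.5)
  expect_error(bv_design(t1, t2, rg = 0.5, mode = "same_sample"), "rp")
  expect_error(bv_design(t1, qt_design(3000, h2 = 0.5), rg = 0.5,
                         mode = "same_sample", rp = 0.3), "equal n")
  expect_error(bv_design(t1, t2, rg = 0.5, mode = "different_samples",
                         rp = 0.3), "rp")
  expect_error(bv_design(qt_design(4000, h2 = 0), t2, rg = 0.5,
                         mode = "different_samples"), "h2")
  d <- bv_design(t1, qt_design(6000, h2 = 0.4), rg = 0.3,
                 mode = "different_samples")
  expect_equal(se_rg(d), se_rg_diff_samples(4000, 6000, 0.5, 0.4, 0.3))
})
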