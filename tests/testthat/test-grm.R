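test_that("GRM entries match hand arithmetic on tiny examples", {
  # all-heterozygous pair at p = 0.5: centered genotypes are 0, so A = 0
  g <- genotype_matrix(rbind(c(1, 1, 1), c(1, 1, 1)),
                       freqs = c(0.5, 0.5, 0.5))
  A <- compute_grm(g)$A
  expect_equal(A[1, 2], 0)
  expect_equal(A[1, 1], 0)
  # single SNP, p = 0.5, genotypes (2, 0): (1)(-1)/0.5 = -2
  g2 <- genotype_matrix(rbind(2, 0), freqs = 0.5)
  grm2 <- compute_grm(g2)
  expect_equal(grm2$A[1, 2], -2)
  expect_equal(grm2$A[1, 1], 2)  # (1)^2/0.5 with the same formula at j = k
})

test_that("GRM is symmetric, invariant to SNP order and allele relabeling", {
  set.seed(11)
  g <- simulate_genotypes(30, 80)
  grm <- compute_grm(g)
  expect_equal(grm$A, t(grm$A))
  perm <- sample(ncol(g$counts))
  g_perm <- genotype_matrix(g$counts[, perm], ids = g$ids,
                            freqs = g$freqs[perm])
  expect_equal(compute_grm(g_perm)$A, grm$A)
  # flip reference allele at half of the SNPs: x -> 2 - x, p -> 1 - p
  flip <- seq(1, 80, by = 2)
  cnt <- g$counts; cnt[, flip] <- 2 - cnt[, flip]
  frq <- g$freqs; frq[flip] <- 1 - frq[flip]
  g_flip <- genotype_matrix(cnt, ids = g$ids, freqs = frq)
  expect_equal(compute_grm(g_flip)$A, grm$A, tolerance = 1e-12)
})

test_that("monomorphic SNPs are dropped and missing data handled per pair", {
  cnt <- rbind(c(2, 0, 1, 2), c(0, 0, 1, NA), c(1, 0, NA, 0))
  g <- genotype_matrix(cnt)
  expect_message(grm <- compute_grm(g), "1 monomorphic")
  expect_equal(grm$m, 3)
  # pair (2,3) shares only SNPs 1 and 4 of the retained three
  expect_equal(grm$n_snps[2, 3], 1)  # SNP 1 only (SNP 3 missing in 3, 4 in 2)
  expect_equal(grm$n_snps[1, 2], 2)
  # a complete-case pair value equals the restricted hand computation
  p <- g$freqs[c(1, 3, 4)]
  w <- function(x, p) (x - 2 * p) / sqrt(2 * p * (1 - p))
  expect_equal(grm$A[1, 2],
               mean(w(c(2, 1), p[1:2]) * w(c(0, 1), p[1:2])))
  expect_error(compute_grm(genotype_matrix(rbind(c(NA, 1), c(1, NA)))),
               "no called SNP")
})

test_that("HWE simulation: diagonal near 1, off-diagonal variance near 1/m", {
  set.seed(21)
  for (m in c(1000, 4000)) {
    grm <- compute_grm(simulate_genotypes(150, m))
    off <- grm$A[upper.tri(grm$A)]
    expect_equal(mean(diag(grm$A)), 1, tolerance = 0.02)
    # with in-sample frequencies each SNP column of standardized genotypes
    # sums to zero, so the off-diagonal total is exactly minus the trace
    expect_equal(2 * sum(off), -sum(diag(grm$A)), tolerance = 1e-10)
    expect_lt(abs(mean(off)), 2 / 150)
    expect_equal(var(off), 1 / m, tolerance = 0.1)
  }
})

test_that("empirical var_pi applies the relatedness cutoff contract", {
  set.seed(31)
  grm <- compute_grm(simulate_genotypes(60, 2000))
  v0 <- empirical_var_pi(grm, relatedness_cutoff = NULL)
  expect_gt(v0, 0)
  # inject one cryptically related pair; the default cutoff removes it
  grm_rel <- grm
  grm_rel$A[5, 12] <- grm_rel$A[12, 5] <- 0.5
  expect_gt(empirical_var_pi(grm_rel, relatedness_cutoff = NULL), v0)
  # default cutoff (0.025) drops the injected pair: result equals the
  # variance of the retained entries computed by hand
  off_rel <- grm_rel$A[upper.tri(grm_rel$A)]
  expect_equal(empirical_var_pi(grm_rel), var(off_rel[off_rel <= 0.025]))
  expect_false(0.5 %in% off_rel[off_rel <= 0.025])
  # constant off-diagonals have zero variance
  grm_const <- grm
  grm_const$A[] <- 0.01
  expect_equal(empirical_var_pi(grm_const), 0)
  expect_error(empirical_var_pi(grm, relatedness_cutoff = -1), "retained")
})

test_that("GCTA text GRM round-trips and reconstructs the full matrix", {
  set.seed(41)
  grm <- compute_grm(simulate_genotypes(15, 40))
  pre <- file.path(tempdir(), "rt")
  write_grm(grm, pre)
  back <- read_grm(pre)
  expect_equal(back$ids, grm$ids)
  expect_lt(max(abs(back$A - grm$A)), 5e-7)  # 6-decimal text round trip
  expect_equal(back$A, t(back$A))
  expect_equal(unname(back$n_snps), unname(grm$n_snps))
  # gzip dialect round-trips too
  pre_gz <- file.path(tempdir(), "rtgz")
  write_grm(grm, pre_gz, gz = TRUE)
  expect_lt(max(abs(read_grm(pre_gz)$A - grm$A)), 5e-7)
})

test_that("malformed GRM files fail with informative errors", {
  pre <- file.path(tempdir(), "bad")
  writeLines(c("1 1 10 1.0", "2 1 10"), paste0(pre, ".grm"))
  writeLines(c("a a", "b b"), paste0(pre, ".grm.id"))
  expect_error(read_grm(pre), "line 2")
  writeLines(c("1 1 10 1.0", "2 1 10 0.1", "2 2 10 1.0", "3 1 10 0.0"),
             paste0(pre, ".grm"))
  expect_error(read_grm(pre), "id file lists 2")
  writeLines(c("1 1 10 1.0", "1 2 10 0.1", "2 2 10 1.0"), paste0(pre, ".grm"))
  expect_error(read_grm(pre), "lower-triangular")
  expect_error(read_grm(file.path(tempdir(), "nonexistent")), "missing")
})

test_that("phenotype files round-trip with missing values", {
  path <- file.path(tempdir(), "toy.phen")
  write_phen(path, ids = c("a", "b", "c"), y = c(1.5, NA, -0.2))
  d <- read_phen(path)
  expect_equal(d$id, c("a", "b", "c"))
  expect_equal(d$y, c(1.5, NA, -0.2))
})
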