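# Naive pair-expansion OLS oracles: materialize every contrast and fit by
# explicit sums.  Deliberately independent of the moment-based code paths.

naive_he_univariate <- function(y, A, standardize = TRUE) {
  if (standardize) y <- (y - mean(y)) / sd(y)
  n <- length(y)
  z <- a <- numeric(0)
  for (j in seq_len(n - 1)) {
    for (k in (j + 1):n) {
      z <- c(z, y[j] * y[k])
      a <- c(a, A[j, k])
    }
  }
  naive_ols(z, a)
}

naive_he_cross <- function(y1, y2, A12, standardize = TRUE) {
  if (standardize) {
    y1 <- (y1 - mean(y1)) / sd(y1)
    y2 <- (y2 - mean(y2)) / sd(y2)
  }
  z <- a <- numeric(0)
  for (i in seq_along(y1)) {
    for (j in seq_along(y2)) {
      z <- c(z, y1[i] * y2[j])
      a <- c(a, A12[i, j])
    }
  }
  naive_ols(z, a)
}

naive_he_cov_same <- function(y1, y2, A, standardize = TRUE) {
  if (standardize) {
    y1 <- (y1 - mean(y1)) / sd(y1)
    y2 <- (y2 - mean(y2)) / sd(y2)
  }
  n <- length(y1)
  z <- a <- numeric(0)
  for (j in seq_len(n - 1)) {
    for (k in (j + 1):n) {
      z <- c(z, (y1[j] * y2[k] + y1[k] * y2[j]) / 2)
      a <- c(a, A[j, k])
    }
  }
  naive_ols(z, a)
}

naive_ols <- function(z, a) {
  np <- length(z)
  b <- sum((z - mean(z)) * (a - mean(a))) / sum((a - mean(a))^2)
  a0 <- mean(z) - b * mean(a)
  resid <- z - a0 - b * a
  var_a <- sum((a - mean(a))^2) / np
  se_emp <- sqrt((sum(resid^2) / np) / (np * var_a))
  list(slope = b, intercept = a0, se_empirical = se_emp)
}
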