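test_that("link support arithmetic and preconditions", {
  sup <- link_support(c(3, 10))
  expect_equal(sup$L_min, c(2L, 9L))
  expect_equal(sup$L_max, c(9L, 100L))
  expect_equal(sup$n_flex, c(7L, 91L))
  expect_equal(sup$n_flex, sup$L_max - sup$L_min)
  expect_error(link_support(1), "richness")
  expect_error(link_support(2.5), "integer")
})

test_that("shifted binomial pmf matches direct enumeration", {
  # boundary point masses
  expect_equal(dshiftbinom(2, 3, p = 0), 1)
  expect_equal(dshiftbinom(9, 3, p = 1), 1)
  # oracle: explicit binomial formula on the shifted count
  expect_equal(dshiftbinom(5, 3, p = 0.5), choose(7, 3) * 0.5^7)
  for (p in c(0.1, 0.5, 0.9)) {
    L <- 2:9
    manual <- choose(7, L - 2) * p^(L - 2) * (1 - p)^(9 - L)
    expect_equal(dshiftbinom(L, 3, p), manual)
  }
  # no mass outside the support
  expect_equal(dshiftbinom(c(1, 10), 3, 0.5), c(0, 0))
  expect_identical(dshiftbinom(1, 3, 0.5, log = TRUE), -Inf)
})

test_that("shifted beta-binomial normalizes over [S-1, S^2]", {
  grid <- expand.grid(S = c(2, 4, 11, 30), mu = c(0.05, 0.086, 0.5, 0.9),
                      phi = c(0.5, 5, 24.3, 200))
  for (i in seq_len(nrow(grid))) {
    S <- grid$S[i]
    tot <- sum(dshiftbetabinom((S - 1):(S^2), S, grid$mu[i], grid$phi[i]))
    expect_equal(tot, 1, tolerance = 1e-10)
  }
  expect_identical(dshiftbetabinom(2, 4, 0.086, 24.3, log = TRUE), -Inf)
})

test_that("closed-form moments match brute-force pmf moments", {
  for (S in c(2, 5, 10, 30)) {
    for (mu in c(0.086, 0.4)) {
      phi <- 24.3
      L <- (S - 1):(S^2)
      pmf <- dshiftbetabinom(L, S, mu, phi)
      mom <- shiftbetabinom_moments(S, mu, phi)
      m1 <- sum(L * pmf)
      m2 <- sum((L - m1)^2 * pmf)
      expect_equal(mom$mean, m1, tolerance = 1e-8)
      expect_equal(mom$variance, m2, tolerance = 1e-8)
    }
  }
  # frozen values from the brute-force oracle at the reported estimates
  mom <- shiftbetabinom_moments(10, 0.086, 24.3)
  expect_equal(mom$mean, 16.826)
  expect_equal(mom$variance, 32.5983, tolerance = 1e-4)
})

test_that("moment boundary behaviour in mu", {
  mom <- shiftbetabinom_moments(10, 1e-9, 24.3)
  expect_equal(mom$mean, 9, tolerance = 1e-6)
  expect_equal(mom$variance, 0, tolerance = 1e-5)
  mom <- shiftbetabinom_moments(10, 1 - 1e-12, 24.3)
  expect_equal(mom$mean, 100, tolerance = 1e-6)
})

test_that("beta-binomial tends to the shifted binomial as phi grows", {
  for (S in c(5, 20)) {
    L <- (S - 1):(S^2)
    bb <- dshiftbetabinom(L, S, mu = 0.3, phi = 1e9)
    sb <- dshiftbinom(L, S, p = 0.3)
    expect_lt(max(abs(bb - sb)), 1e-6)
  }
})

test_that("log-space pmf stays finite for very rich communities", {
  S <- 1000
  lp <- dshiftbetabinom(c(S - 1, 5000, S^2), S, 0.086, 24.3, log = TRUE)
  expect_true(all(is.finite(lp)))
})

test_that("two-stage sampling agrees with analytic moments and CDF", {
  n <- 1e5
  draws <- rshiftbetabinom(n, S = 10, mu = 0.086, phi = 24.3, seed = 7)
  expect_true(all(draws >= 9 & draws <= 100))
  mom <- shiftbetabinom_moments(10, 0.086, 24.3)
  mc_se <- sqrt(mom$variance / n)
  expect_lt(abs(mean(draws) - mom$mean), 3 * mc_se)
  # sup distance between empirical and analytic CDF below the 1% critical
  # value (conservative for a discrete distribution)
  L <- 9:100
  cdf <- cumsum(dshiftbetabinom(L, 10, 0.086, 24.3))
  ecdf_vals <- ecdf(draws)(L)
  expect_lt(max(abs(ecdf_vals - cdf)), 1.628 / sqrt(n))
  # determinism under the seed
  expect_identical(draws, rshiftbetabinom(n, 10, 0.086, 24.3, seed = 7))
  expect_error(rshiftbetabinom(0, 10, 0.086, 24.3), "positive")
})

test_that("negative binomial wrapper is the mean/concentration form", {
  # Poisson limit as kappa grows
  x <- 0:30
  expect_lt(max(abs(dnbinom2(x, 5, 1e9) - dpois(x, 5))), 1e-6)
  # normalization and mean at moderate concentration
  x <- 0:2000
  pmf <- dnbinom2(x, 5, 1.4)
  expect_equal(sum(pmf), 1, tolerance = 1e-10)
  expect_equal(sum(x * pmf), 5, tolerance = 1e-8)
  # variance = m + m^2 / kappa
  expect_equal(sum((x - 5)^2 * pmf), 5 + 25 / 1.4, tolerance = 1e-6)
})

test_that("binomial skewness crosses 0.3 between ten and eleven species", {
  expect_equal(binomial_skewness(10, 0.086), 0.30959, tolerance = 1e-4)
  expect_equal(binomial_skewness(11, 0.086), 0.28032, tolerance = 1e-4)
  expect_gt(binomial_skewness(10, 0.086), 0.3)
  expect_lt(binomial_skewness(11, 0.086), 0.3)
  expect_equal(binomial_skewness(17, 0.5), 0)
  expect_error(binomial_skewness(10, 1), "mu")
})

test_that("sample skewness of binomial draws matches the formula", {
  set.seed(99)
  n_flex <- 10^2 - 10 + 1
  x <- rbinom(1e6, n_flex, 0.086)
  g1 <- mean((x - mean(x))^3) / sd(x)^3
  expect_equal(g1, binomial_skewness(10, 0.086), tolerance = 0.02)
})

test_that("variance of p shrinks with concentration", {
  expect_equal(variance_of_p(0.086, 24.3), 0.0031069, tolerance = 1e-4)
  expect_lt(variance_of_p(0.5, 1e9), 1e-9)
  expect_equal(variance_of_p(0.5, 1e-9), 0.25, tolerance = 1e-6)
})
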