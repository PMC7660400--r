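test_that("connectance and linkage-density bounds are exact", {
  cb <- co_bounds(3)
  expect_equal(cb$min, 2 / 9)
  expect_equal(cb$max, 1)
  lb <- ld_bounds(3)
  expect_equal(lb$min, 2 / 3)
  expect_equal(lb$max, 3)
  # the connectance floor vanishes for rich communities
  expect_lt(co_bounds(10000)$min, 1e-3)
})

test_that("derived densities integrate to one over their support", {
  for (S in c(3, 12, 100)) {
    co <- integrate(dconnectance, (S - 1) / S^2, 1, S = S, mu = 0.086,
                    phi = 24.3, rel.tol = 1e-8)
    expect_equal(co$value, 1, tolerance = 1e-6)
    ld <- integrate(dlinkage_density, (S - 1) / S, S, S = S, mu = 0.086,
                    phi = 24.3, rel.tol = 1e-8)
    expect_equal(ld$value, 1, tolerance = 1e-6)
  }
  expect_equal(dconnectance(0.01, 12, 0.086, 24.3), 0)  # below the floor
})

test_that("derived densities agree with transformed Beta samples", {
  # change-of-variables oracle: sampling p and transforming must match
  # the closed-form shifted/scaled Beta densities
  set.seed(9)
  cases <- data.frame(S = sample(3:200, 20, replace = TRUE),
                      mu = runif(20, 0.03, 0.6),
                      phi = runif(20, 2, 60))
  for (i in seq_len(nrow(cases))) {
    S <- cases$S[i]; mu <- cases$mu[i]; phi <- cases$phi[i]
    p <- rbeta(1e4, mu * phi, (1 - mu) * phi)
    co <- p * (1 - (S - 1) / S^2) + (S - 1) / S^2
    ks_co <- ks.test(co, function(q) {
      pbeta((q - (S - 1) / S^2) / (1 - (S - 1) / S^2), mu * phi,
            (1 - mu) * phi)
    })
    expect_gt(ks_co$p.value, 0.01)
    ld <- p * (S - (S - 1) / S) + (S - 1) / S
    ks_ld <- ks.test(ld, function(q) {
      pbeta((q - (S - 1) / S) / (S - (S - 1) / S), mu * phi,
            (1 - mu) * phi)
    })
    expect_gt(ks_ld$p.value, 0.01)
  }
})

test_that("connectance density converges to the Beta law of p at large S", {
  co <- seq(0.02, 0.4, by = 0.01)
  d_large <- dconnectance(co, 5000, 0.086, 24.3)
  d_beta <- dbeta(co, 0.086 * 24.3, (1 - 0.086) * 24.3)
  expect_lt(max(abs(d_large - d_beta) / d_beta), 0.01)
  # and mean linkage density approaches mu * S (the additive floor
  # (S - 1) / S decays like 1 / (mu * S) in relative terms)
  S <- 5000
  m <- integrate(function(x) x * dlinkage_density(x, S, 0.086, 24.3),
                 (S - 1) / S, S)$value
  expect_equal(m / (0.086 * S), 1, tolerance = 0.005)
})

test_that("normal approximation validity flips between ten and eleven species", {
  na <- normal_approx(c(10, 11), 0.086, 24.3)
  expect_equal(na$normal_ok, c(FALSE, TRUE))
  expect_equal(na$mean, shiftbetabinom_moments(c(10, 11), 0.086, 24.3)$mean)
  expect_true(all(na$mean >= c(9, 10) & na$mean <= c(100, 121)))
})

test_that("normal approximation is close in total variation where valid", {
  # The binomial component is near-normal above ten species; what remains
  # is the skewness of the Beta mixing law (about 1.1 at the fitted mu
  # and phi), which caps how close the normal can get: the total
  # variation distance plateaus below 0.15 and is essentially flat in S,
  # while the first two moments are exact.
  tv <- vapply(c(11, 25, 60), function(S) {
    L <- (S - 1):(S^2)
    pmf <- dshiftbetabinom(L, S, 0.086, 24.3)
    na <- normal_approx(S, 0.086, 24.3)
    approx <- pnorm(L + 0.5, na$mean, na$sd) - pnorm(L - 0.5, na$mean, na$sd)
    sum(abs(pmf - approx)) / 2
  }, numeric(1))
  expect_true(all(tv < 0.15))
  expect_lt(max(tv) - min(tv), 0.02)
  # with a concentrated mixing law the approximation becomes excellent
  L <- 10:121
  pmf <- dshiftbetabinom(L, 11, 0.086, 5000)
  na <- normal_approx(11, 0.086, 5000)
  approx <- pnorm(L + 0.5, na$mean, na$sd) - pnorm(L - 0.5, na$mean, na$sd)
  expect_lt(sum(abs(pmf - approx)) / 2, 0.05)
})

test_that("Z-scores behave as standardized deviations", {
  # a web at the expected link count scores exactly zero
  mom <- shiftbetabinom_moments(12, 0.086, 24.3)
  z0 <- link_zscore(mom$mean, 12, 0.086, 24.3)
  expect_equal(z0$z, 0)
  expect_false(z0$flagged)
  # frozen value from independent evaluation of the moment formulas
  z <- link_zscore(30, 10, 0.086, 24.3)
  expect_equal(z$z, 2.3074, tolerance = 1e-4)
  expect_true(z$flagged)
  # monotone increasing in the observed link count
  zz <- link_zscore(c(10, 20, 30, 50), 10, 0.086, 24.3)
  expect_true(all(diff(zz$z) > 0))
})

test_that("minimum-link webs are never flagged as link-poor", {
  S <- 3:750
  z <- link_zscore(S - 1, S, 0.086, 24.3)
  expect_true(all(z$z > -1.96))
  expect_true(all(z$z < 0))
})

test_that("Z-scores of in-model webs are approximately standard normal", {
  set.seed(31)
  S <- sample(11:400, 1e4, replace = TRUE)
  L <- rshiftbetabinom(1e4, S, 0.086, 24.3)
  z <- link_zscore(L, S, 0.086, 24.3)
  expect_lt(abs(mean(z$z)), 0.05)
  expect_gt(sd(z$z), 0.9)
  expect_lt(sd(z$z), 1.1)
  # the upper-tail exceedance sits near the 2.5% normal reference,
  # inflated somewhat by the right skew of the mixing law
  expect_gt(mean(z$z > 1.96), 0.01)
  expect_lt(mean(z$z > 1.96), 0.06)
})

test_that("zscore_webs keeps identities and handles empty input", {
  webs <- mangal_like_webs(30, seed = 91)
  z <- zscore_webs(webs, 0.086, 24.3)
  expect_equal(z$web_id, webs$web_id)
  expect_equal(nrow(z), 30)
  s <- zscore_summary(z)
  expect_equal(s$n_high + s$n_low, sum(z$flagged))
  empty <- zscore_webs(tibble::tibble(S = integer(), L = integer()),
                       0.086, 24.3)
  expect_equal(nrow(empty), 0)
})

test_that("posterior-predictive intervals are coherent and seeded", {
  fit <- shared_fl_fit()
  iv <- predict_links(fit, S_grid = round(exp(seq(log(3), log(750),
                                                 length.out = 8))),
                      ndraws = 500, seed = 17)
  # nesting: 78% interval inside 97%, median inside both
  expect_true(all(iv$lo97 <= iv$lo78 & iv$hi78 <= iv$hi97))
  expect_true(all(iv$median >= iv$lo78 & iv$median <= iv$hi78))
  expect_true(all(diff(iv$median) > 0))
  expect_identical(iv, predict_links(fit, iv$S, ndraws = 500, seed = 17))
})

test_that("unrealistic-prediction proportions separate the models", {
  S_grid <- c(3:20, 50, 100, 750)
  # flexible links cannot leave the support
  fl <- prop_unrealistic("flexible_links", S_grid)
  expect_true(all(fl$prop == 0))
  # link-species scaling misses for every richness
  lssl <- prop_unrealistic("lssl", S_grid)
  expect_true(all(lssl$prop > 0.2))
  # constant connectance fails mostly in small communities
  cc <- prop_unrealistic("constant_connectance", 3:40)
  expect_true(all(diff(cc$prop) < 0))
  expect_gt(cc$prop[cc$S == 3], 0.5)
  expect_gt(cc$prop[cc$S == 11], 0.2)
  expect_lt(cc$prop[cc$S == 40], 0.05)
  # posterior mode agrees with the analytic masses for a fitted model
  fit <- shared_fl_fit()
  post <- prop_unrealistic(fit, S_grid = c(5, 50), mode = "posterior",
                           ndraws = 400, seed = 3)
  expect_true(all(post$prop == 0))
})
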