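test_that("sampling is deterministic under a fixed seed", {
  webs <- mangal_like_webs(40, seed = 3)
  f1 <- fit_quick(webs, "flexible_links", seed = 11, iter = 400)
  f2 <- fit_quick(webs, "flexible_links", seed = 11, iter = 400)
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_quick(webs, "flexible_links", seed = 12, iter = 400)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("the flexible-links fit recovers its generating parameters", {
  fit <- shared_fl_fit()
  td <- generics::tidy(fit)
  mu_row <- td[td$term == "mu", ]
  phi_row <- td[td$term == "phi", ]
  # 3 posterior SDs: the check is against one realized dataset, whose own
  # sampling noise is on the same scale as the posterior SD
  expect_lt(abs(mu_row$estimate - 0.086), 3 * mu_row$std.error)
  expect_lt(abs(phi_row$estimate - 24.3), 3 * phi_row$std.error)
  expect_true(all(td$rhat < 1.02))
  expect_true(all(td$ess > 100))
})

test_that("simulation-based calibration holds across all four models", {
  # Generating parameters are drawn from each model's prior, so the
  # 2-posterior-SD interval should cover the truth in the large majority
  # of replicates.
  n_rep <- 5
  for (nm in c("flexible_links", "lssl", "constant_connectance",
               "power_law")) {
    m <- fw_model(nm)
    hits <- 0L
    for (r in seq_len(n_rep)) {
      set.seed(3000 + 17 * r)
      repeat {
        theta_raw <- drop(flexlinks:::draw_prior(m, 1))
        names(theta_raw) <- m$params$raw
        theta <- transform_pars(m, theta_raw)
        if (m$obs != "nbinom" || m$mean_fun(750, as.list(theta)) < 1e7) break
      }
      S <- sample_richness(255, "empirical_like")
      webs <- simulate_webs(m, theta = theta, S = S)
      fit <- fit_quick(webs, m, seed = 4000 + r)
      td <- generics::tidy(fit)
      ok <- abs(td$estimate - theta[td$term]) <= 2 * td$std.error
      if (all(ok)) hits <- hits + 1L
    }
    expect_gte(hits, ceiling(0.8 * n_rep))
  }
})

test_that("posterior-predictive flexible links never leave the support", {
  fit <- shared_fl_fit()
  iv <- predict_links(fit, S_grid = c(3, 10, 100, 750), ndraws = 500,
                      seed = 5)
  expect_true(all(iv$lo97 >= iv$S - 1))
  expect_true(all(iv$hi97 <= iv$S^2))
})

test_that("split-chain diagnostics behave on constructed cases", {
  set.seed(123)
  iid <- matrix(rnorm(4000), 1000, 4)
  expect_lt(abs(rhat(iid) - 1), 0.01)
  expect_gt(abs(ess(iid) / 4000), 0.9)
  expect_lt(abs(ess(iid) / 4000), 1.1)
  # a chain with a shifted mean must be flagged
  shifted <- cbind(iid[, 1:3], iid[, 4] + 3)
  expect_gt(rhat(shifted), 1.1)
  # strong autocorrelation cuts the effective sample size
  ar <- matrix(0, 1000, 4)
  for (j in 1:4) ar[, j] <- as.numeric(arima.sim(list(ar = 0.9), 1000))
  expect_lt(ess(ar), 1500)
})

test_that("MAP estimation recovers parameters and matches MLE under flat priors", {
  webs <- cached("map_webs", {
    simulate_webs("flexible_links",
                  S = sample_richness(400, "empirical_like", seed = 21),
                  seed = 22)
  })
  map <- fit_map(webs, "flexible_links", seed = 31)
  expect_lt(abs(map$theta[["mu"]] - 0.086) / 0.086, 0.05)
  expect_lt(abs(map$theta[["phi"]] - 24.3) / 24.3, 0.25)
  # flatten the priors: MAP must coincide with MLE by definition
  flat <- fw_model("flexible_links")
  flat$params$prior <- c("beta", "normal")
  flat$params$prior_a <- c(1, 0)
  flat$params$prior_b <- c(1, 10)
  map_flat <- fit_map(webs, flat, seed = 32)
  mle <- fit_mle(webs, "flexible_links", seed = 33)
  expect_equal(map_flat$theta, mle$theta, tolerance = 1e-3)
})

test_that("MLE of the shifted binomial recovers p via the closed form", {
  set.seed(77)
  S <- rep(c(5L, 12L, 30L), each = 40)
  p_true <- 0.3
  L <- rbinom(length(S), S^2 - S + 1, p_true) + S - 1L
  # closed-form proportion estimator
  p_closed <- sum(L - S + 1) / sum(S^2 - S + 1)
  # numeric MLE from the package's kernel
  p_opt <- optimize(function(p) -sum(dshiftbinom(L, S, p, log = TRUE)),
                    c(1e-6, 1 - 1e-6), tol = 1e-9)$minimum
  expect_equal(p_opt, p_closed, tolerance = 1e-5)
  expect_lt(abs(p_opt - p_true), 0.01)
})

test_that("MLE is invariant to the ordering of the webs", {
  webs <- simulate_webs("lssl", S = sample_richness(120, seed = 41),
                        seed = 42)
  m1 <- fit_mle(webs, "lssl", seed = 43)
  m2 <- fit_mle(webs[rev(seq_len(nrow(webs))), ], "lssl", seed = 43)
  expect_equal(m1$theta, m2$theta, tolerance = 1e-5)
})

test_that("fit reports serialize to JSON with seed and diagnostics", {
  fit <- shared_fl_fit()
  path <- withr::local_tempfile(fileext = ".json")
  fit_report_json(fit, path)
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(rep$sampler$seed, fit$seed)
  expect_equal(rep$model, "flexible_links")
  expect_named(rep$diagnostics$rhat, c("mu", "phi"))
  expect_equal(rep$posterior$estimate[rep$posterior$term == "mu"],
               mean(fit$draws$mu))
})
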