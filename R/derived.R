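#' Bounds on connectance and linkage density
#'
#' Because `S - 1 <= L <= S^2`, connectance `Co = L / S^2` is bounded by
#' `(S - 1) / S^2` and 1, and linkage density `LD = L / S` by
#' `(S - 1) / S` and `S`.
#'
#' @param S Integer species richness (`>= 2`).
#' @return A tibble with columns `S`, `min`, `max`.
#' @name structural_bounds
#' @examples
#' co_bounds(3)
#' ld_bounds(3)
#' @export
co_bounds <- function(S) {
  check_richness(S)
  tibble::tibble(S = as.integer(S), min = (S - 1) / S^2, max = 1)
}

#' @rdname structural_bounds
#' @export
ld_bounds <- function(S) {
  check_richness(S)
  tibble::tibble(S = as.integer(S), min = (S - 1) / S, max = as.numeric(S))
}

#' Probability density of connectance under the flexible-links model
#'
#' Connectance is a linear transformation of the flexible-link probability
#' `p`: `Co = p (1 - (S-1)/S^2) + (S-1)/S^2`. Since
#' `p ~ Beta(mu phi, (1-mu) phi)`, `Co` follows the same Beta shifted to
#' `[(S-1)/S^2, 1]`; the density is zero outside that interval. As `S`
#' grows the support tends to `[0, 1]` and the density converges to the
#' Beta density of `p` itself.
#'
#' @param co Connectance values.
#' @param S Single species richness (`>= 2`).
#' @inheritParams dshiftbetabinom
#' @return Numeric densities.
#' @export
dconnectance <- function(co, S, mu, phi) {
  check_richness(S)
  check_flex_params(mu, phi)
  c0 <- (S - 1) / S^2
  r <- 1 - c0
  stats::dbeta((co - c0) / r, mu * phi, (1 - mu) * phi) / r
}

#' Probability density of linkage density under the flexible-links model
#'
#' `LD = p (S - (S-1)/S) + (S-1)/S`: a Beta distribution shifted and
#' scaled to `[(S-1)/S, S]`. For large `S` its mean approaches `mu * S`.
#'
#' @param ld Linkage-density values.
#' @inheritParams dconnectance
#' @return Numeric densities.
#' @export
dlinkage_density <- function(ld, S, mu, phi) {
  check_richness(S)
  check_flex_params(mu, phi)
  l0 <- (S - 1) / S
  r <- S - l0
  stats::dbeta((ld - l0) / r, mu * phi, (1 - mu) * phi) / r
}

#' Normal approximation to the link distribution
#'
#' The shifted beta-binomial is well approximated by
#' `Normal(mean, variance)` with the moments of
#' [shiftbetabinom_moments()]. The approximation is considered adequate
#' when the absolute binomial skewness ([binomial_skewness()]) is below
#' 0.3; at `mu = 0.086` this requires more than about ten species.
#'
#' @inheritParams shiftbetabinom_moments
#' @param skew_threshold Maximum absolute skewness for `normal_ok`.
#' @return A tibble with columns `S`, `mean`, `sd`, `variance`,
#'   `skewness`, `normal_ok`.
#' @export
normal_approx <- function(S, mu, phi, skew_threshold = 0.3) {
  mom <- shiftbetabinom_moments(S, mu, phi)
  sk <- binomial_skewness(S, mu)
  tibble::tibble(
    S = mom$S, mean = mom$mean, sd = sqrt(mom$variance),
    variance = mom$variance, skewness = sk,
    normal_ok = abs(sk) < skew_threshold
  )
}

#' Analytic Z-scores for observed link counts
#'
#' How many standard deviations an observed link count lies from the
#' population expectation under the flexible-links model:
#' `z = (L - mean) / sd` with the normal-approximation moments. A web with
#' `L` equal to the expectation scores exactly 0; `|z| > critical` (1.96
#' by default) flags webs with surprisingly many or few links, replacing
#' simulation-based null-model tests with a closed form.
#'
#' `link_zscore()` works on vectors of `(L, S)`; `zscore_webs()` on a
#' data frame of webs (keeping `web_id` if present) and is the tabular
#' interface used by the command-line `zscore` command.
#'
#' @param L Observed link counts.
#' @inheritParams shiftbetabinom_moments
#' @param critical Two-sided flagging threshold on `|z|`.
#' @return A tibble of class `fw_zscores` with columns (`web_id`,) `S`,
#'   `L`, `mean`, `sd`, `z`, `flagged`.
#' @examples
#' link_zscore(30, 10, mu = 0.086, phi = 24.3)
#' @export
link_zscore <- function(L, S, mu, phi, critical = 1.96) {
  mom <- normal_approx(S, mu, phi)
  z <- (L - mom$mean) / mom$sd
  out <- tibble::tibble(
    S = as.integer(S), L = L, mean = mom$mean, sd = mom$sd, z = z,
    flagged = abs(z) > critical
  )
  class(out) <- c("fw_zscores", class(out))
  out
}

#' @rdname link_zscore
#' @param data A data frame of webs with columns `S`, `L` and optionally
#'   `web_id`.
#' @export
zscore_webs <- function(data, mu, phi, critical = 1.96) {
  if (nrow(data) == 0) {
    out <- tibble::tibble(S = integer(), L = integer(), mean = numeric(),
                          sd = numeric(), z = numeric(), flagged = logical())
    class(out) <- c("fw_zscores", class(out))
    return(out)
  }
  data <- validate_webs(data)
  out <- link_zscore(data$L, data$S, mu, phi, critical = critical)
  if (!is.null(data$web_id)) {
    out <- dplyr::bind_cols(tibble::tibble(web_id = data$web_id), out)
  }
  class(out) <- c("fw_zscores", class(out))
  out
}

#' Summary counts of flagged Z-scores
#'
#' @param z An `fw_zscores` tibble.
#' @param critical Two-sided threshold.
#' @return One-row tibble: `n`, `n_high` (z above `critical`), `n_low`
#'   (z below `-critical`), `prop_high`, `prop_low`.
#' @export
zscore_summary <- function(z, critical = 1.96) {
  tibble::tibble(
    n = nrow(z),
    n_high = sum(z$z > critical),
    n_low = sum(z$z < -critical),
    prop_high = mean(z$z > critical),
    prop_low = mean(z$z < -critical)
  )
}

interval_summary <- function(df, var, value) {
  out <- dplyr::summarise(
    dplyr::group_by(df, dplyr::across(dplyr::all_of(var))),
    median = stats::median(.data[[value]]),
    lo78 = stats::quantile(.data[[value]], 0.11, names = FALSE),
    hi78 = stats::quantile(.data[[value]], 0.89, names = FALSE),
    lo97 = stats::quantile(.data[[value]], 0.015, names = FALSE),
    hi97 = stats::quantile(.data[[value]], 0.985, names = FALSE),
    .groups = "drop"
  )
  class(out) <- c("fw_intervals", class(out))
  attr(out, "grid_var") <- var
  attr(out, "value_var") <- value
  out
}

posterior_theta_draws <- function(fit, ndraws) {
  pars <- fit$model$params$natural
  m <- as.matrix(fit$draws[pars])
  idx <- sample.int(nrow(m), ndraws, replace = ndraws > nrow(m))
  m[idx, , drop = FALSE]
}

# Vectorized posterior-predictive link counts at a single richness:
# one draw of L per row of the parameter matrix `th`.
sim_links_theta <- function(model, s, th) {
  theta <- as.list(as.data.frame(th))
  n <- nrow(th)
  if (model$obs == "nbinom") {
    rnbinom2(n, mean = model$mean_fun(s, theta), kappa = theta$kappa)
  } else {
    p <- stats::rbeta(n, theta$mu * theta$phi, (1 - theta$mu) * theta$phi)
    stats::rbinom(n, size = s^2 - s + 1, prob = p) + s - 1
  }
}

#' Posterior-predictive link counts over a richness grid
#'
#' For each richness in `S_grid`, draws parameters from the posterior and
#' link counts from the observation model, then summarizes the predictive
#' distribution by its median and the 78% (11-89 percentile) and 97%
#' (1.5-98.5 percentile) equal-tail intervals.
#'
#' @param fit An [fit_bayes()] result (any of the four models).
#' @param S_grid Integer richness values.
#' @param ndraws Posterior-predictive draws per richness value.
#' @param seed Integer seed.
#' @return An `fw_intervals` tibble with columns `S`, `median`, `lo78`,
#'   `hi78`, `lo97`, `hi97`. Supports [autoplot()].
#' @export
predict_links <- function(fit, S_grid, ndraws = 1000, seed = 1) {
  check_richness(S_grid)
  set.seed(seed)
  draws <- purrr::map_dfr(as.integer(S_grid), function(s) {
    th <- posterior_theta_draws(fit, ndraws)
    tibble::tibble(S = s, L = sim_links_theta(fit$model, s, th))
  })
  interval_summary(draws, "S", "L")
}

#' Proportion of ecologically unrealistic link predictions
#'
#' Fraction of predicted link counts falling outside `[S - 1, S^2]` for
#' each richness. Two modes:
#' \describe{
#'   \item{`"analytic"`}{exact tail masses of the negative binomial at
#'     point estimates (`P(L < S - 1) + P(L > S^2)`); deterministic. The
#'     flexible-links model returns exactly 0 by construction.}
#'   \item{`"posterior"`}{Monte-Carlo over posterior(-predictive) draws,
#'     integrating parameter uncertainty.}
#' }
#'
#' @param model An [fw_model()] or model name (analytic mode) or an
#'   `fw_fit` (either mode).
#' @param S_grid Integer richness values.
#' @param mode `"analytic"` or `"posterior"`.
#' @param theta Named natural-scale parameters for analytic mode (defaults
#'   to [mangal_estimates()] for the model, or the posterior means of a
#'   fit).
#' @param ndraws,seed Posterior mode Monte-Carlo settings.
#' @return A tibble with columns `S` and `prop` (in `[0, 1]`).
#' @examples
#' prop_unrealistic("lssl", S_grid = c(3, 10, 100))
#' @export
prop_unrealistic <- function(model, S_grid, mode = c("analytic", "posterior"),
                             theta = NULL, ndraws = 1000, seed = 1) {
  mode <- match.arg(mode)
  check_richness(S_grid)
  S_grid <- as.integer(S_grid)
  fit <- NULL
  if (inherits(model, "fw_fit")) {
    fit <- model
    model <- fit$model
  } else if (is.character(model)) {
    model <- fw_model(model)
  }
  if (mode == "analytic") {
    if (is.null(theta)) {
      theta <- if (!is.null(fit)) {
        pars <- model$params$natural
        stats::setNames(colMeans(as.matrix(fit$draws[pars])), pars)
      } else {
        estimates_for(model$name)
      }
    }
    if (model$obs == "betabinom") {
      return(tibble::tibble(S = S_grid, prop = 0))
    }
    prop <- vapply(S_grid, function(s) {
      m <- model$mean_fun(s, theta)
      pnbinom2(s - 2, m, theta[["kappa"]]) +
        pnbinom2(s^2, m, theta[["kappa"]], lower.tail = FALSE)
    }, numeric(1))
    return(tibble::tibble(S = S_grid, prop = prop))
  }
  if (is.null(fit)) {
    rlang::abort("Posterior mode needs an `fw_fit`; use mode = \"analytic\" for point estimates.")
  }
  set.seed(seed)
  prop <- vapply(S_grid, function(s) {
    L <- sim_links_theta(model, s, posterior_theta_draws(fit, ndraws))
    mean(L < s - 1 | L > s^2)
  }, numeric(1))
  tibble::tibble(S = S_grid, prop = prop)
}
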