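#' Ecologically permitted support for the number of trophic links
#'
#' A food web with `S` species has at least `S - 1` trophic links (every
#' species interacts at least once, e.g. a linear food chain) and at most
#' `S^2` (every ordered species pair interacts, including cannibalism).
#' The `S^2 - S + 1` links in excess of the guaranteed minimum are the
#' "flexible" links, each modelled as a Bernoulli trial.
#'
#' @param S Integer vector of species richness values, all `>= 2`.
#'
#' @return A tibble with one row per element of `S` and columns `S`,
#'   `L_min` (`S - 1`), `L_max` (`S^2`) and `n_flex` (`S^2 - S + 1`, the
#'   number of Bernoulli trials).
#'
#' @examples
#' link_support(c(3, 10))
#' @export
link_support <- function(S) {
  check_richness(S)
  S <- as.integer(S)
  tibble::tibble(
    S = S,
    L_min = S - 1L,
    L_max = as.integer(S)^2L,
    n_flex = as.integer(S)^2L - S + 1L
  )
}

check_richness <- function(S, min = 2) {
  if (length(S) == 0 || anyNA(S) || !is.numeric(S)) {
    rlang::abort("`S` must be a non-empty numeric vector with no missing values.")
  }
  if (any(S != floor(S)) || any(S < min)) {
    rlang::abort(sprintf("`S` must contain integers >= %d (species richness).", min))
  }
  invisible(S)
}

check_flex_params <- function(mu, phi) {
  if (any(!is.finite(mu)) || any(mu <= 0) || any(mu >= 1)) {
    rlang::abort("`mu` must lie strictly in (0, 1).")
  }
  if (any(!is.finite(phi)) || any(phi <= 0)) {
    rlang::abort("`phi` must be a positive concentration.")
  }
  invisible(NULL)
}

#' Shifted binomial distribution for link counts
#'
#' Density of the shifted binomial model for the number of links `L` among
#' `S` species: `L - (S - 1)` realised flexible links out of `S^2 - S + 1`
#' trials, each with success probability `p`. Mass is zero outside
#' `[S - 1, S^2]`.
#'
#' @param L Integer link counts.
#' @param S Integer species richness (`>= 2`); recycled against `L`.
#' @param p Probability that a flexible link is realised, in `[0, 1]`.
#' @param log Return log density?
#'
#' @return Numeric vector of (log) probabilities.
#' @examples
#' dshiftbinom(5, S = 3, p = 0.5)  # choose(7, 3) * 0.5^7
#' @export
dshiftbinom <- function(L, S, p, log = FALSE) {
  check_richness(S)
  n <- S^2 - S + 1
  k <- L - (S - 1)
  out <- stats::dbinom(k, size = n, prob = p, log = TRUE)
  out[L != floor(L) | k < 0 | k > n] <- -Inf
  if (log) out else exp(out)
}

#' Shifted beta-binomial distribution for link counts
#'
#' The flexible-links model: the probability `p` that a flexible link is
#' realised varies across food webs as `Beta(mu * phi, (1 - mu) * phi)`,
#' and conditional on `p` the count of realised flexible links
#' `L - (S - 1)` is binomial with `S^2 - S + 1` trials. Marginally
#' `L - (S - 1)` is beta-binomial; `L` has support exactly `[S - 1, S^2]`.
#'
#' All computation is in log space through [lbeta()] and [lchoose()], so
#' the density is usable for `S` well beyond 750 without overflow.
#'
#' @inheritParams dshiftbinom
#' @param mu Mean of `p` across webs, in (0, 1).
#' @param phi Concentration of `p` around `mu`; `var(p) = mu(1-mu)/(1+phi)`.
#'
#' @return Numeric vector of (log) probabilities.
#' @seealso [shiftbetabinom_moments()], [rshiftbetabinom()]
#' @examples
#' sum(dshiftbetabinom(3:16, S = 4, mu = 0.086, phi = 24.3))  # == 1
#' @export
dshiftbetabinom <- function(L, S, mu, phi, log = FALSE) {
  check_richness(S)
  check_flex_params(mu, phi)
  n <- S^2 - S + 1
  k <- L - (S - 1)
  a <- mu * phi
  b <- (1 - mu) * phi
  out <- lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b)
  out[L != floor(L) | k < 0 | k > n] <- -Inf
  if (log) out else exp(out)
}

#' Mean and variance of the shifted beta-binomial link distribution
#'
#' @inheritParams dshiftbetabinom
#' @return A tibble with columns `S`, `mean` and `variance`:
#'   `mean = (S^2 - S + 1) mu + S - 1` and
#'   `variance = (S^2 - S + 1) mu (1 - mu) (1 + S(S-1) / (phi + 1))`.
#' @examples
#' shiftbetabinom_moments(10, mu = 0.086, phi = 24.3)
#' @export
shiftbetabinom_moments <- function(S, mu, phi) {
  check_richness(S)
  check_flex_params(mu, phi)
  n <- S^2 - S + 1
  tibble::tibble(
    S = as.integer(S),
    mean = n * mu + S - 1,
    variance = n * mu * (1 - mu) * (1 + S * (S - 1) / (phi + 1))
  )
}

#' Sample link counts from the flexible-links model
#'
#' Two-stage sampling: `p ~ Beta(mu * phi, (1 - mu) * phi)` per draw, then
#' `L - (S - 1) ~ Binomial(S^2 - S + 1, p)`. Draws always lie in
#' `[S - 1, S^2]`.
#'
#' @param n Number of draws (positive integer).
#' @param S Species richness; scalar or length-`n` vector.
#' @inheritParams dshiftbetabinom
#' @param seed Optional integer seed for reproducibility.
#'
#' @return Integer vector of `n` link counts.
#' @export
rshiftbetabinom <- function(n, S, mu, phi, seed = NULL) {
  if (length(n) != 1 || !is.finite(n) || n <= 0 || n != floor(n)) {
    rlang::abort("`n` must be a single positive integer.")
  }
  check_richness(S)
  check_flex_params(mu, phi)
  if (!is.null(seed)) set.seed(seed)
  S <- rep_len(as.integer(S), n)
  p <- stats::rbeta(n, mu * phi, (1 - mu) * phi)
  ntr <- S^2 - S + 1
  stats::rbinom(n, size = ntr, prob = p) + S - 1L
}

#' Negative binomial density in mean/concentration form
#'
#' The "NB2" parameterization used for the classical link-count models:
#' mean `mean` and concentration `kappa`, with
#' `variance = mean + mean^2 / kappa`. Larger `kappa` concentrates `L`
#' around the model mean; as `kappa -> Inf` the distribution tends to
#' Poisson. Thin wrappers over [stats::dnbinom()] and friends with
#' `size = kappa`.
#'
#' @param x,q Integer counts (support `x >= 0`).
#' @param mean Positive mean.
#' @param kappa Positive concentration.
#' @param log,log.p,lower.tail As in [stats::dnbinom()].
#' @param n Number of draws.
#'
#' @return Density, distribution function or random draws.
#' @name nbinom2
#' @export
dnbinom2 <- function(x, mean, kappa, log = FALSE) {
  stats::dnbinom(x, mu = mean, size = kappa, log = log)
}

#' @rdname nbinom2
#' @export
pnbinom2 <- function(q, mean, kappa, lower.tail = TRUE, log.p = FALSE) {
  stats::pnbinom(q, mu = mean, size = kappa, lower.tail = lower.tail, log.p = log.p)
}

#' @rdname nbinom2
#' @export
rnbinom2 <- function(n, mean, kappa) {
  stats::rnbinom(n, mu = mean, size = kappa)
}

#' Skewness of the binomial approximation to the link distribution
#'
#' Standard binomial skewness `(1 - 2 mu) / sqrt(n mu (1 - mu))` with
#' `n = S^2 - S + 1` trials. The normal approximation to the link
#' distribution is considered adequate when the absolute skewness is below
#' 0.3; at `mu = 0.086` this happens for communities of more than about
#' ten species.
#'
#' @inheritParams dshiftbetabinom
#' @return Numeric skewness, one value per element of `S`.
#' @examples
#' binomial_skewness(10:11, mu = 0.086)
#' @export
binomial_skewness <- function(S, mu) {
  check_richness(S)
  if (any(mu <= 0) || any(mu >= 1)) {
    rlang::abort("`mu` must lie strictly in (0, 1) for the skewness to exist.")
  }
  n <- S^2 - S + 1
  (1 - 2 * mu) / sqrt(n * mu * (1 - mu))
}

#' Between-web variance of the probability of a flexible link
#'
#' Under the `Beta(mu * phi, (1 - mu) * phi)` mixing law,
#' `var(p) = mu (1 - mu) / (1 + phi)`.
#'
#' @inheritParams dshiftbetabinom
#' @return Numeric variance of `p`.
#' @examples
#' variance_of_p(0.086, 24.3)  # approximately 0.003
#' @export
variance_of_p <- function(mu, phi) {
  check_flex_params(mu, phi)
  mu * (1 - mu) / (1 + phi)
}
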