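#' Mean functions of the four link-count models
#'
#' Expected number of links as a function of species richness under the
#' link-species scaling model (`b * S`), the constant connectance model
#' (`b * S^2`), the power law (`b * S^a`), and the flexible-links model
#' (`p * (S^2 - S + 1) + S - 1`). The power law reduces to link-species
#' scaling at `a = 1` and to constant connectance at `a = 2`.
#'
#' @param S Species richness.
#' @param b Slope / proportionality constant (natural scale).
#' @param a Power-law scaling exponent.
#' @param p Probability that a flexible link is realised, in `[0, 1]`.
#'
#' @return Numeric vector of expected link counts.
#' @name model_means
#' @examples
#' lssl_mean(10, 2.2)
#' fl_mean(10, 0.086)
NULL

#' @rdname model_means
#' @export
lssl_mean <- function(S, b) b * S

#' @rdname model_means
#' @export
cc_mean <- function(S, b) b * S^2

#' @rdname model_means
#' @export
pl_mean <- function(S, a, b) b * S^a

#' @rdname model_means
#' @export
fl_mean <- function(S, p) p * (S^2 - S + 1) + S - 1

model_names <- c("flexible_links", "lssl", "constant_connectance", "power_law")

#' Model specification for a link-count model
#'
#' Declarative description of one of the four Bayesian models: raw
#' (sampling-scale) parameter names, the monotone transform to the natural
#' scale, priors on the raw scale, the mean function and the observation
#' likelihood. The three classical models use a negative binomial
#' observation model (mean/concentration form); the flexible-links model
#' uses the shifted beta-binomial.
#'
#' Parameters with an `exp` transform are sampled on the log scale with a
#' normal prior and reported after exponentiation (`b` of the link-species
#' scaling and power-law models, all concentrations `kappa` and `phi`);
#' `b` of constant connectance and `mu` of flexible links carry Beta(3, 7)
#' priors directly on the unit interval, and the power-law exponent `a`
#' a Normal(2, 0.6) prior.
#'
#' @param name One of `"flexible_links"`, `"lssl"`,
#'   `"constant_connectance"`, `"power_law"`.
#'
#' @return An object of class `fw_model`: a list with elements `name`,
#'   `label`, `params` (a tibble describing raw parameters, transforms and
#'   priors), `mean_fun`, `loglik_fun` and `sim_fun`.
#' @examples
#' fw_model("flexible_links")
#' @export
fw_model <- function(name = model_names) {
  name <- match.arg(name)
  spec <- switch(name,
    lssl = list(
      label = "link-species scaling (b S)",
      params = tibble::tibble(
        raw = c("log_b", "log_kappa"),
        natural = c("b", "kappa"),
        transform = c("exp", "exp"),
        prior = c("normal", "normal"),
        prior_a = c(0.7, 2),
        prior_b = c(0.02, 1),
        lower = c(-Inf, -Inf),
        upper = c(Inf, Inf)
      ),
      mean_fun = function(S, theta) lssl_mean(S, theta[["b"]]),
      obs = "nbinom"
    ),
    constant_connectance = list(
      label = "constant connectance (b S^2)",
      params = tibble::tibble(
        raw = c("b", "log_kappa"),
        natural = c("b", "kappa"),
        transform = c("identity", "exp"),
        prior = c("beta", "normal"),
        prior_a = c(3, 2),
        prior_b = c(7, 1),
        lower = c(0, -Inf),
        upper = c(1, Inf)
      ),
      mean_fun = function(S, theta) cc_mean(S, theta[["b"]]),
      obs = "nbinom"
    ),
    power_law = list(
      label = "power law (b S^a)",
      params = tibble::tibble(
        raw = c("log_b", "a", "log_kappa"),
        natural = c("b", "a", "kappa"),
        transform = c("exp", "identity", "exp"),
        prior = c("normal", "normal", "normal"),
        prior_a = c(-3, 2, 2),
        prior_b = c(1, 0.6, 1),
        lower = c(-Inf, -Inf, -Inf),
        upper = c(Inf, Inf, Inf)
      ),
      mean_fun = function(S, theta) pl_mean(S, theta[["a"]], theta[["b"]]),
      obs = "nbinom"
    ),
    flexible_links = list(
      label = "flexible links (shifted beta-binomial)",
      params = tibble::tibble(
        raw = c("mu", "log_phi"),
        natural = c("mu", "phi"),
        transform = c("identity", "exp"),
        prior = c("beta", "normal"),
        prior_a = c(3, 3),
        prior_b = c(7, 0.5),
        lower = c(0, -Inf),
        upper = c(1, Inf)
      ),
      mean_fun = function(S, theta) fl_mean(S, theta[["mu"]]),
      obs = "betabinom"
    )
  )
  spec$name <- name
  if (spec$obs == "nbinom") {
    spec$loglik_fun <- function(L, S, theta) {
      dnbinom2(L, mean = spec$mean_fun(S, theta), kappa = theta[["kappa"]],
               log = TRUE)
    }
    spec$sim_fun <- function(S, theta) {
      rnbinom2(length(S), mean = spec$mean_fun(S, theta),
               kappa = theta[["kappa"]])
    }
  } else {
    spec$loglik_fun <- function(L, S, theta) {
      dshiftbetabinom(L, S, mu = theta[["mu"]], phi = theta[["phi"]],
                      log = TRUE)
    }
    spec$sim_fun <- function(S, theta) {
      rshiftbetabinom(length(S), S, mu = theta[["mu"]], phi = theta[["phi"]])
    }
  }
  class(spec) <- "fw_model"
  spec
}

#' @export
print.fw_model <- function(x, ...) {
  cat("<fw_model>", x$label, "\n")
  cat("observation model:",
      if (x$obs == "nbinom") "negative binomial (mean/concentration)"
      else "shifted beta-binomial", "\n")
  print(x$params)
  invisible(x)
}

#' All four model specifications
#'
#' @return Named list of [fw_model()] objects in the order flexible links,
#'   link-species scaling, constant connectance, power law.
#' @export
fw_models <- function() {
  stats::setNames(lapply(model_names, fw_model), model_names)
}

#' Map raw (sampling-scale) parameters to the natural scale and back
#'
#' @param model An [fw_model()] specification.
#' @param theta_raw,theta Named numeric vector of raw / natural parameters.
#' @return Named numeric vector on the other scale.
#' @name transform_pars
#' @export
transform_pars <- function(model, theta_raw) {
  p <- model$params
  out <- ifelse(p$transform == "exp", exp(theta_raw[p$raw]),
                theta_raw[p$raw])
  stats::setNames(as.numeric(out), p$natural)
}

#' @rdname transform_pars
#' @export
untransform_pars <- function(model, theta) {
  p <- model$params
  out <- ifelse(p$transform == "exp", log(theta[p$natural]),
                theta[p$natural])
  stats::setNames(as.numeric(out), p$raw)
}

#' Log prior density on the raw scale
#'
#' Sum of the log prior densities of all raw parameters, exactly as the
#' models are defined: normal priors for log-scale parameters, Beta(3, 7)
#' for unit-interval parameters. Out-of-domain values yield `-Inf`.
#'
#' @inheritParams transform_pars
#' @return A single log density.
#' @export
log_prior <- function(model, theta_raw) {
  p <- model$params
  x <- theta_raw[p$raw]
  if (anyNA(x)) rlang::abort("`theta_raw` must name every raw parameter.")
  if (any(x < p$lower | x > p$upper)) return(-Inf)
  lp <- numeric(nrow(p))
  for (i in seq_len(nrow(p))) {
    lp[i] <- switch(p$prior[i],
      normal = stats::dnorm(x[i], p$prior_a[i], p$prior_b[i], log = TRUE),
      beta = stats::dbeta(x[i], p$prior_a[i], p$prior_b[i], log = TRUE)
    )
  }
  sum(lp)
}

draw_prior <- function(model, n = 1) {
  p <- model$params
  draws <- matrix(NA_real_, n, nrow(p), dimnames = list(NULL, p$raw))
  for (i in seq_len(nrow(p))) {
    draws[, i] <- switch(p$prior[i],
      normal = stats::rnorm(n, p$prior_a[i], p$prior_b[i]),
      beta = stats::rbeta(n, p$prior_a[i], p$prior_b[i])
    )
  }
  draws
}

#' Per-web log likelihood
#'
#' Log density of each observed link count under a model at natural-scale
#' parameters: negative binomial on `L` for the classical models, shifted
#' beta-binomial for flexible links (which is `-Inf` for any web with `L`
#' outside `[S - 1, S^2]`).
#'
#' @param data A data frame with integer columns `S` and `L`.
#' @inheritParams transform_pars
#' @return Numeric vector, one log likelihood per row of `data`.
#' @export
pointwise_loglik <- function(data, model, theta) {
  model$loglik_fun(data$L, data$S, theta)
}

#' Unnormalized log posterior on the raw scale
#'
#' `log_prior(model, theta_raw) + sum(pointwise_loglik(...))` with the
#' transform to the natural scale applied for the likelihood. The priors
#' are placed on the raw parameters themselves, so no Jacobian term
#' appears.
#'
#' @inheritParams pointwise_loglik
#' @inheritParams transform_pars
#' @return A single log density (possibly `-Inf`).
#' @export
log_posterior <- function(data, model, theta_raw) {
  lp <- log_prior(model, theta_raw)
  if (!is.finite(lp)) return(-Inf)
  ll <- sum(pointwise_loglik(data, model, transform_pars(model, theta_raw)))
  if (is.nan(ll)) ll <- -Inf
  lp + ll
}

#' Prior predictive simulation of link counts
#'
#' Draw parameters from the priors, then link counts from the observation
#' model, at each supplied richness. Used to check that the priors
#' generate a wide range of link counts without piling mass on webs of
#' minimum or maximum connectance.
#'
#' @inheritParams pointwise_loglik
#' @param S Integer vector of richness values.
#' @param ndraws Number of prior draws.
#' @param seed Optional integer seed.
#' @return A tibble with columns `draw`, `S`, `L` and the natural-scale
#'   parameters used for each draw.
#' @export
prior_predictive <- function(model, S, ndraws = 1000, seed = NULL) {
  check_richness(S)
  if (!is.null(seed)) set.seed(seed)
  raw <- draw_prior(model, ndraws)
  purrr::map_dfr(seq_len(ndraws), function(i) {
    theta <- transform_pars(model, raw[i, ])
    tibble::tibble(
      draw = i, S = as.integer(S),
      L = as.integer(model$sim_fun(as.integer(S), theta)),
      !!!as.list(theta)
    )
  })
}

#' Validate a table of food webs for model fitting
#'
#' Checks the `(S, L)` pairs: integer types, `S >= 2`, `L >= 0`, and — for
#' the flexible-links model, whose likelihood has no mass outside
#' `[S - 1, S^2]` — that every web respects those bounds. Out-of-bounds
#' webs would make the posterior identically zero, so they are an error by
#' default; `on_invalid = "drop"` removes them with a warning instead.
#'
#' @inheritParams pointwise_loglik
#' @param on_invalid `"error"` (default) or `"drop"` for webs violating
#'   the flexible-links bounds.
#' @return The validated (possibly reduced) tibble, invisibly usable in
#'   pipes.
#' @export
validate_webs <- function(data, model = NULL, on_invalid = c("error", "drop")) {
  on_invalid <- match.arg(on_invalid)
  if (!all(c("S", "L") %in% names(data))) {
    rlang::abort("`data` must have columns `S` and `L`.")
  }
  if (nrow(data) == 0) rlang::abort("`data` has no rows.")
  if (anyNA(data$S) || anyNA(data$L) ||
      any(data$S != floor(data$S)) || any(data$L != floor(data$L))) {
    rlang::abort("`S` and `L` must be integers with no missing values.")
  }
  if (any(data$S < 2)) rlang::abort("All webs need `S >= 2`.")
  if (any(data$L < 0)) rlang::abort("All webs need `L >= 0`.")
  needs_bounds <- !is.null(model) && inherits(model, "fw_model") &&
    model$obs == "betabinom"
  if (needs_bounds) {
    bad <- data$L < data$S - 1 | data$L > data$S^2
    if (any(bad)) {
      msg <- sprintf(
        "%d web(s) have L outside [S - 1, S^2]; the flexible-links likelihood is zero there.",
        sum(bad))
      if (on_invalid == "error") {
        rlang::abort(paste(msg, "Use on_invalid = \"drop\" to exclude them."))
      }
      rlang::warn(paste(msg, "Dropping them."))
      data <- data[!bad, , drop = FALSE]
      if (nrow(data) == 0) rlang::abort("No webs left after dropping.")
    }
  }
  tibble::as_tibble(data)
}

#' Serialize a model specification to JSON and back
#'
#' The specification (name, parameter names, transforms and priors) is
#' written as plain JSON so a fit can be reproduced bit-for-bit from its
#' report. Reading reconstructs the canonical [fw_model()] and verifies
#' the stored priors match.
#'
#' @inheritParams transform_pars
#' @param path File path.
#' @return `model_to_json()` returns `path` invisibly; `model_from_json()`
#'   an [fw_model()].
#' @name model_json
#' @export
model_to_json <- function(model, path) {
  jsonlite::write_json(
    list(name = model$name, label = model$label, params = model$params),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname model_json
#' @export
model_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- fw_model(obj$name)
  cols <- c("raw", "natural", "transform", "prior", "prior_a", "prior_b")
  stored <- tibble::as_tibble(obj$params)[cols]
  stored$prior_a <- as.numeric(stored$prior_a)
  stored$prior_b <- as.numeric(stored$prior_b)
  if (!isTRUE(all.equal(as.data.frame(stored),
                        as.data.frame(model$params[cols]),
                        check.attributes = FALSE))) {
    rlang::abort("Stored priors do not match this version of the model.")
  }
  model
}

#' Reported point estimates for the mangal.io food-web compilation
#'
#' Posterior means and standard deviations (natural scale) obtained when
#' the four models are fit to the 255 predation/herbivory networks of the
#' mangal.io database. These are convenient reference parameters for
#' simulation and for the derived-quantity functions.
#'
#' @return A tibble with columns `model`, `parameter`, `estimate`, `sd`.
#' @examples
#' mangal_estimates()
#' @export
mangal_estimates <- function() {
  tibble::tribble(
    ~model, ~parameter, ~estimate, ~sd,
    "lssl", "b", 2.2, 0.047,
    "lssl", "kappa", 1.4, 0.12,
    "constant_connectance", "b", 0.12, 0.0041,
    "constant_connectance", "kappa", 4.0, 0.37,
    "power_law", "b", 0.37, 0.054,
    "power_law", "a", 1.7, 0.043,
    "power_law", "kappa", 4.8, 0.41,
    "flexible_links", "mu", 0.086, 0.0037,
    "flexible_links", "phi", 24.3, 2.4
  )
}

estimates_for <- function(name) {
  est <- mangal_estimates()
  est <- est[est$model == name, ]
  stats::setNames(est$estimate, est$parameter)
}
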