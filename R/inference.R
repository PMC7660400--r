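#' Fit a link-count model by MCMC
#'
#' Samples the posterior of a link-count model with a seeded adaptive
#' random-walk Metropolis sampler. During warmup the proposal covariance
#' is adapted to the history of the chain (Haario-style) and a global
#' scale is tuned toward a 30% acceptance rate; after warmup the kernel is
#' frozen, so post-warmup draws target the exact posterior. The models
#' have at most three parameters, for which a tuned random walk mixes
#' well; convergence should still be confirmed with [rhat()] / [ess()]
#' (reported by [tidy()]).
#'
#' Defaults are four chains of 2,000 iterations each, half of which is
#' warmup. Chains are initialized from prior draws and are fully
#' reproducible given `seed`.
#'
#' @param data A data frame of food webs with integer columns `S` and `L`
#'   (see [validate_webs()]).
#' @param model An [fw_model()] specification or a model name.
#' @param chains Number of chains.
#' @param iter Iterations per chain (warmup included).
#' @param warmup Warmup iterations per chain; default `iter / 2`.
#' @param seed Integer seed; required for reproducibility.
#' @param on_invalid Passed to [validate_webs()].
#'
#' @return An object of class `fw_fit` with elements `draws` (tibble:
#'   `.chain`, `.iteration`, natural-scale parameters, `lp__`),
#'   `draws_raw` (matrix of raw-scale draws), `model`, `data`, and sampler
#'   metadata. Supports [tidy()], [glance()], [autoplot()].
#' @examples
#' \donttest{
#' webs <- mangal_like_webs(60, seed = 1)
#' fit <- fit_bayes(webs, "flexible_links", chains = 2, iter = 600, seed = 1)
#' tidy(fit)
#' }
#' @export
fit_bayes <- function(data, model, chains = 4, iter = 2000,
                      warmup = floor(iter / 2), seed = 1,
                      on_invalid = c("error", "drop")) {
  if (is.character(model)) model <- fw_model(model)
  data <- validate_webs(data, model, on_invalid = match.arg(on_invalid))
  if (chains < 1 || iter <= warmup) {
    rlang::abort("Need `chains >= 1` and `iter > warmup`.")
  }
  lp_fun <- function(theta_raw) log_posterior(data, model, theta_raw)
  d <- nrow(model$params)
  par_names <- model$params$raw

  chain_list <- vector("list", chains)
  for (ch in seq_len(chains)) {
    set.seed(seed + 1000003L * ch)
    init <- NULL
    for (try in 1:100) {
      cand <- drop(draw_prior(model, 1))
      names(cand) <- par_names
      if (is.finite(lp_fun(cand))) { init <- cand; break }
    }
    if (is.null(init)) {
      rlang::abort(
        "Could not find a finite log posterior from prior draws; check the data (see validate_webs()).")
    }
    chain_list[[ch]] <- rwm_chain(lp_fun, init, iter, warmup,
                                  init_scale = prior_scales(model))
  }

  raw <- do.call(rbind, lapply(chain_list, `[[`, "draws"))
  colnames(raw) <- par_names
  n_keep <- iter - warmup
  natural <- vapply(seq_len(nrow(raw)), function(i) {
    transform_pars(model, raw[i, ])
  }, numeric(d))
  natural <- t(natural)
  colnames(natural) <- model$params$natural
  draws <- tibble::as_tibble(as.data.frame(natural))
  draws$lp__ <- unlist(lapply(chain_list, `[[`, "lp"))
  draws <- dplyr::bind_cols(
    tibble::tibble(
      .chain = rep(seq_len(chains), each = n_keep),
      .iteration = rep(seq_len(n_keep), chains)
    ),
    draws
  )

  structure(
    list(
      draws = draws,
      draws_raw = raw,
      model = model,
      data = data,
      chains = chains,
      iter = iter,
      warmup = warmup,
      seed = seed,
      accept_rate = vapply(chain_list, `[[`, numeric(1), "accept_rate")
    ),
    class = "fw_fit"
  )
}

# Per-parameter prior standard deviations: the starting proposal scale.
prior_scales <- function(model) {
  p <- model$params
  ifelse(p$prior == "normal", p$prior_b,
         sqrt(p$prior_a * p$prior_b /
                ((p$prior_a + p$prior_b)^2 * (p$prior_a + p$prior_b + 1))))
}

# Adaptive random-walk Metropolis for one chain. RNG state is set by the
# caller. Adaptation (covariance from the accumulated history, scale by
# Robbins-Monro toward 30% acceptance) happens only during warmup.
rwm_chain <- function(lp_fun, init, iter, warmup, init_scale = NULL) {
  d <- length(init)
  par_names <- names(init)
  cur <- init
  cur_lp <- lp_fun(cur)
  log_s <- log(2.38 / sqrt(d))
  chol_sigma <- if (is.null(init_scale)) diag(d) else
    diag(init_scale, nrow = d)
  hist <- matrix(NA_real_, warmup, d)
  keep <- matrix(NA_real_, iter - warmup, d)
  keep_lp <- numeric(iter - warmup)
  n_acc <- 0L
  for (t in seq_len(iter)) {
    prop <- cur + exp(log_s) * drop(chol_sigma %*% stats::rnorm(d))
    names(prop) <- par_names
    prop_lp <- lp_fun(prop)
    alpha <- if (is.finite(prop_lp)) min(1, exp(prop_lp - cur_lp)) else 0
    if (stats::runif(1) < alpha) {
      cur <- prop; cur_lp <- prop_lp
      if (t > warmup) n_acc <- n_acc + 1L
    }
    if (t <= warmup) {
      hist[t, ] <- cur
      log_s <- log_s + (alpha - 0.3) / sqrt(t)
      if (t >= 100 && t %% 50 == 0) {
        sig <- stats::cov(hist[floor(t / 2):t, , drop = FALSE]) +
          diag(1e-10, d)
        ch <- tryCatch(chol(sig), error = function(e) NULL)
        if (!is.null(ch)) chol_sigma <- t(ch)
      }
    } else {
      keep[t - warmup, ] <- cur
      keep_lp[t - warmup] <- cur_lp
    }
  }
  list(draws = keep, lp = keep_lp,
       accept_rate = n_acc / (iter - warmup))
}

as_chain_array <- function(fit, scale = c("natural", "raw")) {
  scale <- match.arg(scale)
  n <- fit$iter - fit$warmup
  pars <- if (scale == "natural") fit$model$params$natural else
    fit$model$params$raw
  if (scale == "natural") {
    m <- as.matrix(fit$draws[pars])
  } else {
    m <- fit$draws_raw
  }
  lapply(stats::setNames(pars, pars), function(p) {
    matrix(m[, p], nrow = n, ncol = fit$chains)
  })
}

#' Split-chain rank-normalized R-hat
#'
#' Each chain is split in half, all draws are rank-normalized, and the
#' classical potential-scale-reduction factor is computed on the normal
#' scores; the reported value is the maximum of the bulk statistic and the
#' same statistic on folded (absolute-deviation-from-median) scores.
#' Values near 1 indicate mixing; above about 1.01 warrants more
#' iterations.
#'
#' @param x An `fw_fit` or a numeric matrix (iterations x chains).
#' @param ... Unused.
#' @return For a fit, a named vector (one entry per natural-scale
#'   parameter); for a matrix, a single value.
#' @export
rhat <- function(x, ...) UseMethod("rhat")

#' @export
rhat.fw_fit <- function(x, ...) {
  vapply(as_chain_array(x), rhat.matrix, numeric(1))
}

#' @export
rhat.matrix <- function(x, ...) {
  z <- rank_normalize(split_chains(x))
  zf <- rank_normalize(abs(split_chains(x) - stats::median(x)))
  max(rhat_basic(z), rhat_basic(zf))
}

#' Effective sample size
#'
#' Geyer initial-monotone-sequence effective sample size computed on
#' rank-normalized split chains.
#'
#' @inheritParams rhat
#' @return As [rhat()].
#' @export
ess <- function(x, ...) UseMethod("ess")

#' @export
ess.fw_fit <- function(x, ...) {
  vapply(as_chain_array(x), ess.matrix, numeric(1))
}

#' @export
ess.matrix <- function(x, ...) {
  ess_basic(rank_normalize(split_chains(x)))
}

split_chains <- function(m) {
  n <- nrow(m)
  h <- floor(n / 2)
  cbind(m[seq_len(h), , drop = FALSE],
        m[(n - h + 1):n, , drop = FALSE])
}

rank_normalize <- function(m) {
  r <- rank(as.vector(m), ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (length(r) + 1 / 4))
  matrix(z, nrow = nrow(m))
}

rhat_basic <- function(m) {
  n <- nrow(m)
  mu <- colMeans(m)
  B <- n * stats::var(mu)
  W <- mean(apply(m, 2, stats::var))
  if (W < 1e-300) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

ess_basic <- function(m) {
  n <- nrow(m)
  M <- ncol(m)
  W <- mean(apply(m, 2, stats::var))
  B <- n * stats::var(colMeans(m))
  var_plus <- W * (n - 1) / n + B / n
  if (var_plus < 1e-300) return(M * n)
  # mean autocovariance across chains
  acov <- sapply(seq_len(M), function(j) {
    stats::acf(m[, j], lag.max = n - 1, type = "covariance",
               plot = FALSE, demean = TRUE)$acf[, 1, 1]
  })
  acov <- rowMeans(acov) * (n - 1) / n
  rho <- 1 - (W - acov) / var_plus
  # Geyer: sum over pairs while the pair sums stay positive and monotone
  max_pairs <- floor((n - 1) / 2)
  tau <- 1
  prev_pair <- Inf
  for (k in seq_len(max_pairs)) {
    pair <- rho[2 * k] + rho[2 * k + 1]
    if (!is.finite(pair) || pair < 0) break
    pair <- min(pair, prev_pair)
    prev_pair <- pair
    tau <- tau + 2 * pair
  }
  min(M * n, M * n / tau)
}

#' @export
print.fw_fit <- function(x, ...) {
  cat("<fw_fit>", x$model$label, "\n")
  cat(sprintf("%d webs | %d chains x %d iterations (%d warmup) | seed %d\n",
              nrow(x$data), x$chains, x$iter, x$warmup, x$seed))
  print(generics::tidy(x))
  invisible(x)
}

#' Tidy posterior summaries of a model fit
#'
#' One row per natural-scale parameter with posterior mean, SD, equal-tail
#' percentile intervals, and convergence diagnostics.
#'
#' @param x An `fw_fit`.
#' @param conf.level Width of the reported interval (default 0.97, i.e.
#'   percentiles 1.5 and 98.5).
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`, `rhat`, `ess`.
#' @method tidy fw_fit
#' @export
tidy.fw_fit <- function(x, conf.level = 0.97, ...) {
  pars <- x$model$params$natural
  lo <- (1 - conf.level) / 2
  rh <- rhat(x)
  es <- ess(x)
  purrr::map_dfr(pars, function(p) {
    v <- x$draws[[p]]
    tibble::tibble(
      term = p,
      estimate = mean(v),
      std.error = stats::sd(v),
      conf.low = stats::quantile(v, lo, names = FALSE),
      conf.high = stats::quantile(v, 1 - lo, names = FALSE),
      rhat = rh[[p]],
      ess = es[[p]]
    )
  })
}

#' One-row fit summary
#'
#' @param x An `fw_fit`.
#' @param ... Unused.
#' @return A tibble with the model name, data size, draw counts, the worst
#'   R-hat and smallest ESS across parameters, and the mean acceptance
#'   rate.
#' @method glance fw_fit
#' @export
glance.fw_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model$name,
    n_webs = nrow(x$data),
    chains = x$chains,
    draws = x$chains * (x$iter - x$warmup),
    max_rhat = max(rhat(x)),
    min_ess = min(ess(x)),
    accept_rate = mean(x$accept_rate),
    seed = x$seed
  )
}

#' Serialize a fit report to JSON
#'
#' Writes model name, priors, sampler settings (seed included), posterior
#' summaries on the natural scale and convergence diagnostics as plain
#' JSON, sufficient to reproduce the fit from the same data file.
#'
#' @param fit An `fw_fit`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
fit_report_json <- function(fit, path) {
  jsonlite::write_json(
    list(
      model = fit$model$name,
      priors = fit$model$params,
      sampler = list(algorithm = "adaptive random-walk Metropolis",
                     chains = fit$chains, iter = fit$iter,
                     warmup = fit$warmup, seed = fit$seed,
                     accept_rate = fit$accept_rate),
      posterior = generics::tidy(fit),
      diagnostics = list(rhat = as.list(rhat(fit)), ess = as.list(ess(fit)))
    ),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

optimize_objective <- function(data, model, objective, n_starts = 8,
                               seed = 1) {
  d <- nrow(model$params)
  set.seed(seed)
  starts <- draw_prior(model, n_starts)
  lower <- model$params$lower
  upper <- model$params$upper
  eps <- 1e-8
  lower <- ifelse(is.finite(lower), lower + eps, -Inf)
  upper <- ifelse(is.finite(upper), upper - eps, Inf)
  best <- NULL
  for (i in seq_len(n_starts)) {
    th0 <- pmin(pmax(starts[i, ], lower), upper)
    names(th0) <- model$params$raw
    fn <- function(v) {
      names(v) <- model$params$raw
      val <- objective(v)
      if (!is.finite(val)) 1e12 else -val
    }
    res <- tryCatch(
      stats::optim(th0, fn, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) {
      best <- res
    }
  }
  if (is.null(best)) rlang::abort("All optimizer starts failed.")
  theta_raw <- stats::setNames(best$par, model$params$raw)
  list(theta_raw = theta_raw,
       theta = transform_pars(model, theta_raw),
       value = -best$value)
}

#' Maximum a posteriori and maximum likelihood point estimates
#'
#' Bounded quasi-Newton (L-BFGS-B) optimization of the log posterior
#' (`fit_map()`) or log likelihood (`fit_mle()`) on the raw scale, with
#' seeded multi-starts drawn from the priors; the best objective wins.
#' Estimates are reported on the natural scale.
#'
#' @inheritParams fit_bayes
#' @param n_starts Number of seeded starting points.
#' @return An object of class `fw_point`: list with `theta` (natural
#'   scale), `theta_raw`, `value` (achieved objective), `objective`
#'   (`"map"` or `"mle"`), `model`. Supports [tidy()].
#' @name point_estimates
#' @export
fit_map <- function(data, model, n_starts = 8, seed = 1,
                    on_invalid = c("error", "drop")) {
  if (is.character(model)) model <- fw_model(model)
  data <- validate_webs(data, model, on_invalid = match.arg(on_invalid))
  res <- optimize_objective(
    data, model, function(v) log_posterior(data, model, v),
    n_starts = n_starts, seed = seed)
  structure(c(res, list(objective = "map", model = model)),
            class = "fw_point")
}

#' @rdname point_estimates
#' @export
fit_mle <- function(data, model, n_starts = 8, seed = 1,
                    on_invalid = c("error", "drop")) {
  if (is.character(model)) model <- fw_model(model)
  data <- validate_webs(data, model, on_invalid = match.arg(on_invalid))
  res <- optimize_objective(
    data, model,
    function(v) {
      ll <- sum(pointwise_loglik(data, model, transform_pars(model, v)))
      if (is.nan(ll)) -Inf else ll
    },
    n_starts = n_starts, seed = seed)
  structure(c(res, list(objective = "mle", model = model)),
            class = "fw_point")
}

#' @export
print.fw_point <- function(x, ...) {
  cat("<fw_point>", toupper(x$objective), "for", x$model$label, "\n")
  print(generics::tidy(x))
  invisible(x)
}

#' @method tidy fw_point
#' @export
tidy.fw_point <- function(x, ...) {
  tibble::tibble(term = names(x$theta), estimate = as.numeric(x$theta),
                 objective = x$objective, value = x$value)
}
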