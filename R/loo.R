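#' Fit a generalized Pareto distribution to upper-tail exceedances
#'
#' Profile-likelihood estimator of the generalized Pareto shape `k` and
#' scale `sigma` (Zhang-Stephens style quadrature over the profile
#' posterior), with the weakly informative shape regularization that is
#' standard for Pareto-smoothed importance sampling: the raw estimate is
#' shrunk as `(n k + 5) / (n + 10)` toward 0.5.
#'
#' @param x Positive exceedances over the tail cutoff (need not be
#'   sorted).
#' @return A list with elements `k` and `sigma`.
#' @export
gpd_fit <- function(x) {
  x <- sort(as.numeric(x))
  n <- length(x)
  if (n < 5) rlang::abort("Need at least 5 tail values to fit the generalized Pareto distribution.")
  if (x[1] <= 0) rlang::abort("Tail exceedances must be positive.")
  if (x[n] - x[1] < 1e-12 * abs(x[n])) {
    rlang::abort("Tail values are (numerically) constant; degenerate fit.")
  }
  prior_bk <- 3
  m <- 30 + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1, floor(n / 4 + 0.5))]
  # grid over theta = -k/sigma; negative theta corresponds to heavy tails
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (prior_bk * xstar)
  k_of_theta <- vapply(theta, function(th) mean(log1p(-th * x)), numeric(1))
  l_theta <- n * (log(-theta / k_of_theta) - k_of_theta - 1)
  w <- exp(l_theta - max(l_theta))
  w <- w / sum(w)
  theta_hat <- sum(theta * w)
  k <- mean(log1p(-theta_hat * x))
  sigma <- -k / theta_hat
  k <- (n * k + 10 * 0.5) / (n + 10)  # shrink toward 0.5 with prior weight 10
  list(k = k, sigma = sigma)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) -sigma * log1p(-p) else sigma / k * ((1 - p)^(-k) - 1)
}

#' Pareto-smoothed importance weights
#'
#' Stabilizes a vector of log importance ratios by fitting a generalized
#' Pareto distribution to the largest ratios (tail size
#' `min(0.2 n, 3 sqrt(n))`), replacing them with expected order statistics
#' of the fitted tail, and truncating at the raw maximum. Returned weights
#' are normalized in log space.
#'
#' @param log_ratios Numeric vector of log importance ratios, one per
#'   posterior draw.
#' @return A list with `log_weights` (normalized, same length) and
#'   `k` (the fitted Pareto shape; `NA` when the tail is degenerate and no
#'   smoothing was applied). `k > 0.7` indicates an unreliable
#'   importance-sampling estimate.
#' @export
psis_smooth <- function(log_ratios) {
  nd <- length(log_ratios)
  lw <- log_ratios - max(log_ratios)
  M <- ceiling(min(0.2 * nd, 3 * sqrt(nd)))
  k <- NA_real_
  if (M >= 5) {
    ord <- order(lw)
    tail_ids <- ord[(nd - M + 1):nd]
    cutoff <- lw[ord[nd - M]]
    exceed <- exp(lw[tail_ids]) - exp(cutoff)
    smoothable <- max(exceed) - min(exceed) > 1e-12 * max(abs(exceed), 1)
    if (smoothable && all(exceed >= 0) && any(exceed > 0)) {
      fit <- tryCatch(gpd_fit(exceed[exceed > 0]), error = function(e) NULL)
      if (!is.null(fit) && is.finite(fit$k)) {
        k <- fit$k
        qq <- qgpd((seq_len(M) - 0.5) / M, fit$k, fit$sigma)
        smoothed <- log(qq + exp(cutoff))
        smoothed <- pmin(smoothed, 0)  # cap at raw maximum (lw max is 0)
        lw[tail_ids[order(lw[tail_ids])]] <- smoothed
      }
    }
  }
  lw <- lw - log_sum_exp(lw)
  list(log_weights = lw, k = k)
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Pointwise log-likelihood matrix from a fit
#'
#' Evaluates the observation log density of every web at every posterior
#' draw; the input PSIS-LOO needs.
#'
#' @param fit An [fit_bayes()] result.
#' @param data Optional data frame of webs; defaults to the data the model
#'   was fit to.
#' @return A numeric matrix, draws x observations.
#' @export
loglik_matrix <- function(fit, data = NULL) {
  if (is.null(data)) data <- fit$data
  pars <- fit$model$params$natural
  m <- as.matrix(fit$draws[pars])
  out <- matrix(NA_real_, nrow(m), nrow(data))
  for (s in seq_len(nrow(m))) {
    out[s, ] <- pointwise_loglik(data, fit$model,
                                 stats::setNames(m[s, ], pars))
  }
  out
}

#' PSIS-LOO cross-validation
#'
#' Pareto-smoothed importance-sampling approximation to leave-one-out
#' cross-validation. For each observation the importance ratios are the
#' inverse likelihoods; smoothed weights give the expected log predictive
#' density (elpd) contribution. The total elpd, its standard error
#' `sqrt(n var(pointwise))` and the Pareto-k diagnostics are returned,
#' together with the deviance-scale value `looic = -2 elpd` (the scale on
#' which "PSIS-LOO" information criteria are usually printed; smaller is
#' better, while larger elpd is better).
#'
#' @param loglik A draws x observations log-likelihood matrix
#'   ([loglik_matrix()]) or an `fw_fit` (the matrix is computed for its
#'   own data).
#' @param k_threshold Pareto-k value above which an observation is
#'   counted as unreliable (default 0.7).
#' @return An object of class `fw_loo`: list with `elpd`, `se`, `looic`,
#'   `pointwise` (tibble with per-observation `elpd_i` and `pareto_k`),
#'   `n_high_k`, `n_obs`, `n_draws`. Supports [tidy()] and [glance()].
#' @export
psis_loo <- function(loglik, k_threshold = 0.7) {
  if (inherits(loglik, "fw_fit")) {
    model_name <- loglik$model$name
    loglik <- loglik_matrix(loglik)
  } else {
    model_name <- NA_character_
  }
  if (!is.matrix(loglik) || !all(is.finite(loglik))) {
    rlang::abort("`loglik` must be a finite draws x observations matrix.")
  }
  n <- ncol(loglik)
  res <- purrr::map_dfr(seq_len(n), function(i) {
    sm <- psis_smooth(-loglik[, i])
    tibble::tibble(
      obs = i,
      elpd_i = log_sum_exp(sm$log_weights + loglik[, i]),
      pareto_k = sm$k
    )
  })
  elpd <- sum(res$elpd_i)
  se <- sqrt(n * stats::var(res$elpd_i))
  structure(
    list(model = model_name, elpd = elpd, se = se, looic = -2 * elpd,
         pointwise = res,
         n_high_k = sum(res$pareto_k > k_threshold, na.rm = TRUE),
         k_threshold = k_threshold,
         n_obs = n, n_draws = nrow(loglik)),
    class = "fw_loo")
}

#' @export
print.fw_loo <- function(x, ...) {
  cat("<fw_loo>", if (!is.na(x$model)) x$model else "", "\n")
  cat(sprintf("elpd_loo %.1f (SE %.1f) | looic %.1f | %d/%d Pareto-k > %.1f\n",
              x$elpd, x$se, x$looic, x$n_high_k, x$n_obs, x$k_threshold))
  invisible(x)
}

#' @method tidy fw_loo
#' @export
tidy.fw_loo <- function(x, ...) x$pointwise

#' @method glance fw_loo
#' @export
glance.fw_loo <- function(x, ...) {
  tibble::tibble(model = x$model, elpd = x$elpd, se = x$se,
                 looic = x$looic, n_high_k = x$n_high_k, n_obs = x$n_obs)
}

#' Compare models by expected log predictive density
#'
#' Ranks [psis_loo()] results by elpd and reports, for every model, the
#' difference to the best model and the standard error of that difference
#' computed from the pointwise elpd differences (`sqrt(n var(diff))`) —
#' the appropriate uncertainty for paired comparisons on the same webs.
#'
#' @param ... Named `fw_loo` objects, or a single named list of them. All
#'   must cover the same observations.
#' @return A tibble with columns `model`, `elpd`, `se`, `looic`,
#'   `delta_elpd`, `se_delta`, `n_high_k`, sorted best first
#'   (`delta_elpd = 0` for the best model, negative otherwise).
#' @export
loo_compare <- function(...) {
  dots <- list(...)
  if (length(dots) == 1 && !inherits(dots[[1]], "fw_loo")) dots <- dots[[1]]
  if (is.null(names(dots)) || any(names(dots) == "")) {
    nm <- vapply(dots, function(l) l$model, character(1))
    if (anyNA(nm)) rlang::abort("Supply named fw_loo objects.")
    names(dots) <- nm
  }
  n_obs <- unique(vapply(dots, `[[`, numeric(1), "n_obs"))
  if (length(n_obs) != 1) {
    rlang::abort("All models must be evaluated on the same observations.")
  }
  tab <- purrr::imap_dfr(dots, function(l, nm) {
    tibble::tibble(model = nm, elpd = l$elpd, se = l$se, looic = l$looic,
                   n_high_k = l$n_high_k)
  })
  tab <- dplyr::arrange(tab, dplyr::desc(.data$elpd))
  best <- dots[[tab$model[1]]]
  deltas <- purrr::map_dfr(tab$model, function(nm) {
    d <- dots[[nm]]$pointwise$elpd_i - best$pointwise$elpd_i
    tibble::tibble(delta_elpd = sum(d),
                   se_delta = sqrt(n_obs * stats::var(d)))
  })
  dplyr::relocate(dplyr::bind_cols(tab, deltas),
                  "delta_elpd", "se_delta", .after = "se")
}

#' Exact leave-one-out cross-validation by refitting
#'
#' Brute-force elpd: for each observation, refit the model to the data
#' without it and evaluate the log predictive density of the held-out web
#' over the refit posterior. Intended as an independent check of
#' [psis_loo()] on small datasets; cost scales linearly in `n`.
#'
#' @inheritParams fit_bayes
#' @return A list with `elpd` and `pointwise` elpd contributions.
#' @export
exact_loo <- function(data, model, chains = 2, iter = 1000,
                      warmup = floor(iter / 2), seed = 1) {
  if (is.character(model)) model <- fw_model(model)
  data <- validate_webs(data, model)
  elpd_i <- vapply(seq_len(nrow(data)), function(i) {
    fit <- fit_bayes(data[-i, ], model, chains = chains, iter = iter,
                     warmup = warmup, seed = seed + i)
    ll <- loglik_matrix(fit, data[i, , drop = FALSE])[, 1]
    log_sum_exp(ll) - log(length(ll))
  }, numeric(1))
  list(elpd = sum(elpd_i), pointwise = elpd_i)
}
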