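#' Sample species richness values for synthetic food-web tables
#'
#' Empirical compilations of food webs are dominated by small communities
#' with a long tail toward species-rich systems. Two samplers emulate
#' this over the range `[S_min, S_max]` (defaults 3 to 750):
#' \describe{
#'   \item{`"log_uniform"`}{`exp(Uniform(log S_min, log S_max))`, rounded;
#'     median near `sqrt(S_min S_max)` (about 47 for the defaults).}
#'   \item{`"empirical_like"`}{a truncated log-normal with median 30 and
#'     log-scale SD 1.1, a closer stand-in for the observed richness
#'     histogram (most webs a few dozen species).}
#' }
#'
#' @param n Number of draws.
#' @param method `"log_uniform"` (default) or `"empirical_like"`.
#' @param S_min,S_max Integer richness range.
#' @param seed Optional integer seed.
#' @return Integer vector of length `n` within `[S_min, S_max]`.
#' @examples
#' sample_richness(5, seed = 1)
#' @export
sample_richness <- function(n, method = c("log_uniform", "empirical_like"),
                            S_min = 3, S_max = 750, seed = NULL) {
  method <- match.arg(method)
  if (n <= 0 || n != floor(n)) rlang::abort("`n` must be a positive integer.")
  if (S_min < 2 || S_max <= S_min) rlang::abort("Need `2 <= S_min < S_max`.")
  if (!is.null(seed)) set.seed(seed)
  if (method == "log_uniform") {
    S <- round(exp(stats::runif(n, log(S_min), log(S_max))))
  } else {
    S <- integer(0)
    while (length(S) < n) {
      cand <- round(stats::rlnorm(2 * n, meanlog = log(30), sdlog = 1.1))
      S <- c(S, cand[cand >= S_min & cand <= S_max])
    }
    S <- S[seq_len(n)]
  }
  as.integer(pmin(pmax(S, S_min), S_max))
}

#' Simulate a table of food webs from a link-count model
#'
#' Draws one link count per richness value from the observation model at
#' the supplied natural-scale parameters. Flexible-links draws always lie
#' in `[S - 1, S^2]`; draws from the classical models may fall outside
#' those bounds (that is the substantive difference between the models)
#' and are kept, marked by the `in_bounds` column.
#'
#' @param model An [fw_model()] or model name.
#' @param theta Named natural-scale parameters (e.g.
#'   `c(b = 2.2, kappa = 1.4)`); defaults to [mangal_estimates()] for the
#'   model.
#' @param S Integer vector of richness values, one web each (see
#'   [sample_richness()]).
#' @param seed Optional integer seed.
#' @return A tibble with columns `web_id`, `S`, `L`, `in_bounds`.
#' @examples
#' simulate_webs("flexible_links", S = sample_richness(10, seed = 1), seed = 1)
#' @export
simulate_webs <- function(model, theta = NULL, S, seed = NULL) {
  if (is.character(model)) model <- fw_model(model)
  check_richness(S)
  if (is.null(theta)) theta <- estimates_for(model$name)
  if (!all(model$params$natural %in% names(theta))) {
    rlang::abort("`theta` must name every natural-scale parameter.")
  }
  if (!is.null(seed)) set.seed(seed)
  S <- as.integer(S)
  L <- model$sim_fun(S, theta)
  if (all(L <= .Machine$integer.max)) L <- as.integer(L)
  tibble::tibble(
    web_id = sprintf("web_%03d", seq_along(S)),
    S = S, L = L,
    in_bounds = L >= S - 1 & L <= S^2
  )
}

#' Synthetic stand-in for the mangal.io food-web table
#'
#' Convenience wrapper: empirical-like richness values and flexible-links
#' link counts at the reported point estimates (`mu = 0.086`,
#' `phi = 24.3`), yielding a table shaped like the 255-web mangal.io
#' compilation. This is synthetic data — the real compilation must be
#' queried from mangal.io.
#'
#' @param n Number of webs (default 255).
#' @param seed Integer seed.
#' @return A tibble with columns `web_id`, `S`, `L`, `in_bounds`.
#' @examples
#' mangal_like_webs(5, seed = 1)
#' @export
mangal_like_webs <- function(n = 255, seed = 1) {
  S <- sample_richness(n, method = "empirical_like", seed = seed)
  simulate_webs("flexible_links", S = S, seed = seed + 1L)
}
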