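#' Species richness from relative area
#'
#' Power-law species-area relationship `S = k A^z`, with `k` the maximal
#' species richness at relative area `A = 1` and `z` the scaling
#' exponent (defaults `k = 200`, `z = 0.27`). Returns the continuous
#' value; [round_species()] rounds half-up to the integer richness the
#' discrete link models need, and values below 2 are excluded from
#' prediction grids.
#'
#' @param A Positive relative areas.
#' @param k Maximal species richness (`>= 2`).
#' @param z Positive scaling exponent.
#' @return Numeric richness values (not rounded).
#' @examples
#' species_area(c(0.5, 1))
#' @export
species_area <- function(A, k = 200, z = 0.27) {
  if (any(A <= 0)) rlang::abort("`A` must be positive.")
  if (k < 2 || z <= 0) rlang::abort("Need `k >= 2` and `z > 0`.")
  k * A^z
}

#' @rdname species_area
#' @param S Continuous richness values.
#' @export
round_species <- function(S) as.integer(floor(S + 0.5))

#' Network-area relationship for linkage density
#'
#' Converts each area to a species richness via [species_area()], then
#' draws posterior-predictive link counts from the fitted model and
#' summarizes linkage density `LD = L / S` by median, 78% and 97%
#' percentile intervals. Areas whose rounded richness falls below 2 are
#' dropped with a warning.
#'
#' @param fit An [fit_bayes()] result.
#' @param areas Positive relative areas.
#' @inheritParams species_area
#' @param ndraws Posterior-predictive draws per area.
#' @param seed Integer seed.
#' @return An `fw_intervals` tibble with columns `A`, `S` (rounded
#'   richness), `S_real` (pre-rounding), `median`, `lo78`, `hi78`, `lo97`,
#'   `hi97`.
#' @export
nar_linkage_density <- function(fit, areas, k = 200, z = 0.27,
                                ndraws = 1000, seed = 1) {
  S_real <- species_area(areas, k, z)
  S <- round_species(S_real)
  keep <- S >= 2
  if (!all(keep)) {
    rlang::warn("Dropping areas with rounded richness below 2.")
    areas <- areas[keep]; S <- S[keep]; S_real <- S_real[keep]
  }
  set.seed(seed)
  draws <- purrr::map_dfr(seq_along(areas), function(j) {
    L <- sim_links_theta(fit$model, S[j], posterior_theta_draws(fit, ndraws))
    tibble::tibble(A = areas[j], LD = L / S[j])
  })
  out <- interval_summary(draws, "A", "LD")
  out <- dplyr::left_join(
    tibble::tibble(A = areas, S = S, S_real = S_real), out, by = "A")
  class(out) <- c("fw_intervals", class(out))
  attr(out, "grid_var") <- "A"
  attr(out, "value_var") <- "LD"
  out
}

#' Critical interaction-strength standard deviation
#'
#' Under May's criterion a random community matrix with richness `S` and
#' connectance `Co` is stable when `sigma sqrt(S Co) < 1`, where `sigma`
#' is the standard deviation of interaction strengths. Since
#' `S * Co = L / S = LD`, the critical value is `sigma* = 1 / sqrt(LD)`:
#' denser webs tolerate weaker interaction variability.
#'
#' @param LD Positive linkage densities.
#' @return `sigma*` values.
#' @examples
#' sigma_max(c(1, 100))
#' @export
sigma_max <- function(LD) {
  if (any(LD <= 0)) rlang::abort("`LD` must be positive.")
  1 / sqrt(LD)
}

#' Posterior intervals for the critical interaction strength over richness
#'
#' Posterior-predictive draws of `L` at each richness give draws of
#' `sigma* = 1 / sqrt(L / S)`, summarized by median and the 78%/97%
#' percentile intervals. The median declines with richness: larger webs
#' are harder to stabilize.
#'
#' @inheritParams predict_links
#' @return An `fw_intervals` tibble over `S`.
#' @export
sigma_max_curve <- function(fit, S_grid, ndraws = 1000, seed = 1) {
  check_richness(S_grid)
  set.seed(seed)
  draws <- purrr::map_dfr(as.integer(S_grid), function(s) {
    L <- sim_links_theta(fit$model, s, posterior_theta_draws(fit, ndraws))
    tibble::tibble(S = s, sigma_star = sigma_max(pmax(L, 1) / s))
  })
  interval_summary(draws, "S", "sigma_star")
}

#' Probability that a food web of a given richness is stable
#'
#' Fraction of posterior-predictive draws of `L` at richness `S`
#' satisfying May's criterion `sigma sqrt(L / S) < 1` for a given
#' interaction-strength standard deviation `sigma`. The criterion is
#' evaluated per draw, so the probability integrates both parameter and
#' sampling uncertainty. `sigma` has no privileged value and must be
#' supplied explicitly.
#'
#' @param fit An [fit_bayes()] result.
#' @param S Integer richness values.
#' @param sigma Positive interaction-strength standard deviation(s).
#' @param ndraws Posterior-predictive draws per combination.
#' @param seed Integer seed.
#' @return A tibble with columns `S`, `sigma`, `p_stable`.
#' @export
prob_stable <- function(fit, S, sigma, ndraws = 1000, seed = 1) {
  check_richness(S)
  if (any(sigma <= 0)) rlang::abort("`sigma` must be positive.")
  set.seed(seed)
  purrr::map_dfr(as.integer(S), function(s) {
    L <- sim_links_theta(fit$model, s, posterior_theta_draws(fit, ndraws))
    purrr::map_dfr(sigma, function(sg) {
      tibble::tibble(S = s, sigma = sg,
                     p_stable = mean(sg * sqrt(pmax(L, 0) / s) < 1))
    })
  })
}
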