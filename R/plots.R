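#' Plot posterior-predictive interval summaries
#'
#' Ribbon plot of the median and the 78%/97% percentile intervals of a
#' predicted quantity over its grid (richness or area). For link
#' predictions over `S`, the structural bounds `S - 1` and `S^2` are
#' overlaid so implausible predictions are visible at a glance.
#'
#' @param object An `fw_intervals` tibble ([predict_links()],
#'   [nar_linkage_density()], [sigma_max_curve()]).
#' @param data Optional tibble of observed webs (columns `S`, `L`) to
#'   overlay when plotting link predictions.
#' @param log_scale Use log10 axes (default `TRUE`; natural for these
#'   quantities).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fw_intervals
#' @export
autoplot.fw_intervals <- function(object, data = NULL, log_scale = TRUE,
                                  ...) {
  grid_var <- attr(object, "grid_var") %||% names(object)[1]
  value_var <- attr(object, "value_var") %||% "value"
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data[[grid_var]])) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo97, ymax = .data$hi97),
                         fill = "grey85") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo78, ymax = .data$hi78),
                         fill = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = .data$median), colour = "#2166ac") +
    ggplot2::labs(x = grid_var, y = value_var) +
    ggplot2::theme_minimal()
  if (grid_var == "S" && value_var == "L") {
    bounds <- tibble::tibble(S = object$S)
    p <- p +
      ggplot2::geom_line(data = bounds,
                         ggplot2::aes(y = .data$S - 1), linewidth = 0.3) +
      ggplot2::geom_line(data = bounds,
                         ggplot2::aes(y = .data$S^2), linewidth = 0.7)
    if (!is.null(data)) {
      p <- p + ggplot2::geom_point(data = data,
                                   ggplot2::aes(y = .data$L),
                                   colour = "grey40", alpha = 0.6, size = 0.8)
    }
  }
  if (log_scale) {
    p <- p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10()
  }
  p
}

#' Plot posterior parameter densities
#'
#' One density panel per natural-scale parameter, chains pooled.
#'
#' @param object An `fw_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fw_fit
#' @export
autoplot.fw_fit <- function(object, ...) {
  pars <- object$model$params$natural
  long <- tidyr::pivot_longer(object$draws, dplyr::all_of(pars),
                              names_to = "parameter")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_density(fill = "#2166ac", alpha = 0.4) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = NULL, y = "posterior density",
                  title = object$model$label) +
    ggplot2::theme_minimal()
}

#' Plot the distribution of food-web Z-scores
#'
#' Histogram of analytic Z-scores with the flagging thresholds marked;
#' flagged webs are highlighted.
#'
#' @param object An `fw_zscores` tibble ([zscore_webs()]).
#' @param critical Threshold drawn as vertical lines.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fw_zscores
#' @export
autoplot.fw_zscores <- function(object, critical = 1.96, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$z, fill = .data$flagged)) +
    ggplot2::geom_histogram(bins = 40, colour = "white") +
    ggplot2::geom_vline(xintercept = c(-critical, critical),
                        linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "#d6604d"),
                               guide = "none") +
    ggplot2::labs(x = "Z score", y = "number of webs") +
    ggplot2::theme_minimal()
}
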