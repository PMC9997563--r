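# ggplot2 displays for the main result types.

#' Plot interval summaries
#'
#' Food-interaction fraction and (optionally normalized) cumulative distance
#' per 2-minute interval, one panel per measure, one line per well.
#'
#' @param object An `fw_intervals` tibble.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot fw_intervals
#' @export
autoplot.fw_intervals <- function(object, ...) {
  d <- as_tibble(object) |>
    mutate(time_min = (.data$start_s + attr(object, "interval_s") / 2) / 60) |>
    tidyr::pivot_longer(c("food_fraction", "distance_px"),
                        names_to = "measure", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_min, y = .data$value,
                                  colour = .data$well)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~measure, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "Time (min)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot feeding bouts as an ethogram
#'
#' One horizontal track per well; dark segments are denoised feeding bouts.
#'
#' @param object An `fw_bouts` tibble (with a `well` column, e.g. from
#'   [session_bouts()]).
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot fw_bouts
#' @export
autoplot.fw_bouts <- function(object, ...) {
  d <- as_tibble(object)
  if (!"well" %in% names(d)) d$well <- "well"
  ggplot2::ggplot(d) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start_s / 60,
                   xend = (.data$start_s + .data$duration_s) / 60,
                   y = .data$well, yend = .data$well),
      linewidth = 4, colour = "grey20"
    ) +
    ggplot2::labs(x = "Time (min)", y = NULL,
                  title = "Feeding bouts (denoised)") +
    ggplot2::theme_minimal()
}

#' Plot a smoothed trend curve
#'
#' @param object An `fw_trend` tibble from [smooth_trend()].
#' @param points Optional raw `(time, value)` data to underlay.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot fw_trend
#' @export
autoplot.fw_trend <- function(object, points = NULL, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$time, y = .data$fitted))
  if (!is.null(points)) {
    p <- p + ggplot2::geom_point(data = as_tibble(points),
                                 ggplot2::aes(x = .data$time, y = .data$value),
                                 alpha = 0.3, inherit.aes = FALSE)
  }
  p + ggplot2::geom_line(colour = "steelblue", linewidth = 1) +
    ggplot2::labs(x = "Time (min)", y = "Fitted",
                  subtitle = sprintf("loess, span %.2f", attr(object, "span"))) +
    ggplot2::theme_minimal()
}

#' Plot a standard curve with its calibration points
#'
#' @param object An `fw_standard_curve`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot fw_standard_curve
#' @export
autoplot.fw_standard_curve <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$known_amount, y = .data$signal)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(
      x = "Known amount", y = object$signal_kind,
      subtitle = sprintf("signal = %.4g amount + %.4g,  r^2 = %.4f",
                         object$slope, object$intercept, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}
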