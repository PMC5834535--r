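# ggplot2 displays: coherence maps with COI shading and significance
# contours, wind-rose phase histograms, monthly LAI ribbons.

#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_line geom_ribbon
#'   geom_col geom_contour scale_y_continuous scale_fill_viridis_c labs
#'   coord_polar theme_minimal geom_point
NULL

#' @export
ggplot2::autoplot

#' Coherence map with COI shading and significance contour
#'
#' @param object a `wavelet_coherence`.
#' @param ... unused.
#' @return a ggplot: time against log2 period, fill = coherence, shaded
#'   outside the cone of influence, with a contour around significant cells
#'   when a Monte-Carlo test was run.
#' @method autoplot wavelet_coherence
#' @export
autoplot.wavelet_coherence <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot(df, aes(x = .data$date, y = .data$period)) +
    geom_raster(aes(fill = .data$coherence)) +
    geom_raster(data = df[!df$inside_coi, ], fill = "white", alpha = 0.6) +
    geom_line(data = tibble(date = object$dates, period = pmax(object$coi, min(object$periods))),
              aes(y = .data$period), linetype = 2, linewidth = 0.3) +
    scale_y_continuous(trans = "log2", breaks = c(13, 26, 52, 104, 208, 365, 730),
                       name = "period (weeks)") +
    scale_fill_viridis_c(limits = c(0, 1), option = "turbo") +
    labs(x = NULL, fill = "coherence",
         title = sprintf("wavelet coherence: %s ~ %s", object$pair[1], object$pair[2])) +
    theme_minimal()
  if (!is.null(object$significant)) {
    p <- p + geom_contour(aes(z = as.numeric(.data$significant)),
                          breaks = 0.5, colour = "black", linewidth = 0.3)
  }
  p
}

#' Wind-rose display of a phase histogram
#'
#' Positive angles (first series lags) to the right of vertical, negative
#' (first series leads) to the left.
#'
#' @param object a `phase_histogram` (or a `phase_sample`, binned with
#'   defaults).
#' @param ... unused.
#' @return a ggplot in polar coordinates.
#' @method autoplot phase_histogram
#' @export
autoplot.phase_histogram <- function(object, ...) {
  s <- attr(object, "summary")
  ggplot(object, aes(x = .data$bin_mid, y = .data$count)) +
    geom_col(width = 360 / nrow(object), fill = "steelblue", colour = "grey30") +
    coord_polar(start = pi, direction = 1) +
    ggplot2::scale_x_continuous(limits = c(-180, 180),
                                breaks = seq(-180, 135, by = 45)) +
    labs(x = "phase angle (deg; positive = first series lags)", y = "cells",
         subtitle = if (!is.null(s)) {
           sprintf("circular mean %.1f deg +- %.1f deg (n = %d)",
                   s$mean_deg, s$sd_deg, attr(object, "n"))
         }) +
    theme_minimal()
}

#' @method autoplot phase_sample
#' @export
autoplot.phase_sample <- function(object, ...) {
  autoplot(phase_histogram(object), ...)
}

#' Monthly LAI with standard-error ribbon
#'
#' @param object an `lai_monthly` from [aggregate_lai()].
#' @param ... unused.
#' @return a ggplot of monthly mean LAI with a +-1 SE ribbon.
#' @method autoplot lai_monthly
#' @export
autoplot.lai_monthly <- function(object, ...) {
  ggplot(object, aes(x = .data$month, y = .data$lai_mean)) +
    geom_ribbon(aes(ymin = .data$lai_mean - .data$lai_se,
                    ymax = .data$lai_mean + .data$lai_se), alpha = 0.3) +
    geom_line() + geom_point(size = 0.8) +
    labs(x = NULL, y = "leaf area index") +
    theme_minimal()
}
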