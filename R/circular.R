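# Band-restricted phase-angle samples and circular statistics.

#' Select phase angles in a period band
#'
#' Collects the phase cells of a coherence result whose Fourier period lies in
#' `[period_min, period_max]`, that fall inside the cone of influence, and
#' whose coherence strictly exceeds `coh_min` (default 0.5, the conventional
#' threshold for phase interpretation). An empty selection is returned with a
#' warning, not an error.
#'
#' @param object a `wavelet_coherence`.
#' @param period_min,period_max band limits in the period units of the result
#'   (weeks throughout this package).
#' @param coh_min coherence threshold (strict).
#' @param significant_only if `TRUE`, additionally require the Monte-Carlo
#'   significance mask (needs [coherence_significance()]).
#' @return tibble of class `phase_sample` with columns `date`, `time`,
#'   `period`, `coherence`, `angle_deg`; attributes record the band and
#'   selection rule.
#' @export
band_select <- function(object, period_min, period_max, coh_min = 0.5,
                        significant_only = FALSE) {
  stopifnot(inherits(object, "wavelet_coherence"))
  if (!(period_min < period_max)) abort("need period_min < period_max")
  inband <- object$periods >= period_min & object$periods <= period_max
  sel <- object$inside_coi &
    matrix(inband, nrow(object$coherence), ncol(object$coherence), byrow = TRUE) &
    object$coherence > coh_min
  if (significant_only) {
    if (is.null(object$significant)) abort("no significance mask: run coherence_significance()")
    sel <- sel & object$significant
  }
  idx <- which(sel, arr.ind = TRUE)
  out <- tibble(
    date = object$dates[idx[, 1]],
    time = idx[, 1],
    period = object$periods[idx[, 2]],
    coherence = object$coherence[sel],
    angle_deg = object$phase_deg[sel]
  )
  if (nrow(out) == 0L) warn("band_select: empty selection (no qualifying cells)")
  attr(out, "band") <- c(period_min, period_max)
  attr(out, "coh_min") <- coh_min
  attr(out, "pair") <- object$pair
  class(out) <- c("phase_sample", class(out))
  out
}

#' Circular mean and standard deviation of phase angles
#'
#' Summarises a phase sample with circular statistics: the mean is the
#' argument of the (optionally weighted) mean resultant vector, the standard
#' deviation is `sqrt(-2 log R)` (in radians, reported in degrees) where `R`
#' is the mean resultant length. A zero resultant (e.g. antipodal angles)
#' leaves the mean undefined and is an error. The reported `n_eff` is a
#' decorrelation heuristic for the statistically dependent neighbouring
#' time-scale cells: per selected period, the time extent of the selected
#' cells divided by that period, summed over periods (at least 1 per period).
#'
#' @param sample a `phase_sample` from [band_select()], or a data frame with
#'   an `angle_deg` column, or a numeric vector of angles in degrees.
#' @param weights optional nonnegative weights (e.g. coherence); default
#'   unweighted.
#' @return one-row tibble: `mean_deg`, `sd_deg`, `r` (resultant length), `n`,
#'   `n_eff`.
#' @export
circular_mean_sd <- function(sample, weights = NULL) {
  ang <- if (is.data.frame(sample)) sample$angle_deg else as.numeric(sample)
  if (length(ang) == 0L) abort("empty phase sample")
  if (is.null(weights)) weights <- rep(1, length(ang))
  if (any(weights < 0) || !all(is.finite(weights))) abort("weights must be finite and >= 0")
  th <- ang * pi / 180
  w <- weights / sum(weights)
  zc <- sum(w * cos(th)); zs <- sum(w * sin(th))
  r <- sqrt(zc^2 + zs^2)
  if (r < 1e-12) abort("zero resultant length: circular mean undefined")
  mean_deg <- atan2(zs, zc) * 180 / pi
  if (mean_deg <= -180) mean_deg <- mean_deg + 360
  sd_deg <- sqrt(-2 * log(min(r, 1))) * 180 / pi
  n_eff <- NA_real_
  if (is.data.frame(sample) && all(c("time", "period") %in% names(sample))) {
    n_eff <- sample |>
      group_by(.data$period) |>
      summarise(ne = max(1, (max(.data$time) - min(.data$time) + 1) / .data$period[1]),
                .groups = "drop") |>
      pull("ne") |>
      sum()
  }
  tibble(mean_deg = mean_deg, sd_deg = sd_deg, r = r,
         n = length(ang), n_eff = n_eff)
}

#' Convert a phase angle to a time lag (and back)
#'
#' `lag = angle / 360 * period`, with the package-wide sign convention:
#' positive = the first series of the coherence pair lags the second. At the
#' 12-month seasonal band an angle of 30 degrees is 1 month; at a 4-year
#' period the same angle is 4 months.
#'
#' @param angle_deg phase angle(s) in degrees.
#' @param period oscillation period (any time unit; the lag inherits it).
#' @return time lag in the units of `period`.
#' @export
angle_to_lag <- function(angle_deg, period) {
  if (any(period <= 0)) abort("`period` must be > 0")
  angle_deg / 360 * period
}

#' @rdname angle_to_lag
#' @param lag time lag in the units of `period`.
#' @export
lag_to_angle <- function(lag, period) {
  if (any(period <= 0)) abort("`period` must be > 0")
  a <- (lag / period * 360) %% 360
  ifelse(a > 180, a - 360, a)
}

#' Circular histogram of phase angles
#'
#' Bins angles into `n_bins` equal half-open sectors `(lo, hi]` covering the
#' full circle (stored on the (-180, 180] branch; binning is independent of
#' the storage branch). Feed to [autoplot()] for a wind-rose display.
#'
#' @param sample a `phase_sample`, data frame with `angle_deg`, or numeric
#'   vector of degrees.
#' @param n_bins number of angular bins (>= 4), default 16.
#' @return tibble of class `phase_histogram`: `bin_lo`, `bin_hi`, `bin_mid`,
#'   `count`; attributes carry the circular summary ([circular_mean_sd()])
#'   and sample size.
#' @export
phase_histogram <- function(sample, n_bins = 16) {
  if (n_bins < 4) abort("`n_bins` must be >= 4")
  ang <- if (is.data.frame(sample)) sample$angle_deg else as.numeric(sample)
  # normalize to (-180, 180]
  ang <- ang %% 360
  ang[ang > 180] <- ang[ang > 180] - 360
  breaks <- seq(-180, 180, length.out = n_bins + 1)
  bin <- cut(ang, breaks = breaks, right = TRUE, include.lowest = FALSE)
  cnt <- as.integer(table(bin))
  out <- tibble(
    bin_lo = breaks[-length(breaks)],
    bin_hi = breaks[-1],
    bin_mid = (breaks[-length(breaks)] + breaks[-1]) / 2,
    count = cnt
  )
  attr(out, "n") <- length(ang)
  attr(out, "summary") <- if (length(ang)) tryCatch(circular_mean_sd(ang),
                                                    error = function(e) NULL)
  class(out) <- c("phase_histogram", class(out))
  out
}
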