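# Morlet continuous wavelet transform, wavelet coherence and phase.
#
# Shape parameter k0 = 6 (admissibility); with this choice the Fourier period
# equivalent to scale s is lambda = 4*pi*s / (k0 + sqrt(2 + k0^2)) ~ 1.033 s,
# and the e-folding time of the wavelet envelope is sqrt(2) s, which sets the
# cone of influence.

MORLET_K0 <- 6
MORLET_FOURIER_FACTOR <- 4 * pi / (MORLET_K0 + sqrt(2 + MORLET_K0^2))
MORLET_EFOLD <- sqrt(2)

#' Scale grid for the continuous wavelet transform
#'
#' Scales at fractional powers of two: `voices` scales per octave between the
#' Fourier periods `period_min` and `period_max` (default: 8 sampling
#' intervals up to half the record length).
#'
#' @param n series length (needed when `period_max` is NULL).
#' @param dt sampling interval (weeks throughout this package).
#' @param period_min,period_max smallest/largest Fourier period, in units of
#'   `dt` times weeks.
#' @param voices number of scales per octave (default 12).
#' @return list with `scales`, `periods` (both increasing), `dj` (= 1/voices)
#'   and `dt`.
#' @export
scale_grid <- function(n = NULL, dt = 1, period_min = 8 * dt,
                       period_max = NULL, voices = 12) {
  if (is.null(period_max)) {
    if (is.null(n)) abort("supply `n` or `period_max`")
    period_max <- n * dt / 2
  }
  if (period_min <= 0 || period_max <= period_min) {
    abort("need 0 < period_min < period_max")
  }
  s0 <- period_min / MORLET_FOURIER_FACTOR
  J <- floor(voices * log2(period_max / period_min))
  scales <- s0 * 2^((0:J) / voices)
  list(scales = scales, periods = scales * MORLET_FOURIER_FACTOR,
       dj = 1 / voices, dt = dt)
}

#' Cone of influence
#'
#' Per-time maximum Fourier period at which edge effects of the finite record
#' are negligible: the period grows linearly with the distance from the nearer
#' series end, via the Morlet e-folding time sqrt(2) s. At the first and last
#' sample the cone collapses to period zero (nothing is trustworthy there);
#' it is maximal and symmetric at mid-record.
#'
#' @param n series length.
#' @param dt sampling interval.
#' @return numeric vector of length `n`: the COI period at each time step.
#' @export
cone_of_influence <- function(n, dt = 1) {
  d <- pmin(seq_len(n) - 1L, n - seq_len(n))
  MORLET_FOURIER_FACTOR / MORLET_EFOLD * dt * d
}

# Batched CWT engine: X is an n x B numeric matrix (columns are series).
# Returns a list over scales of n x B complex coefficient matrices.
# Zero padding to the next power of two; columns are demeaned first.
cwt_engine <- function(X, dt, scales, demean = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (demean) X <- sweep(X, 2, colMeans(X), "-")
  npad <- 2^ceiling(log2(n)) # zero padding to the next power of two
  Xp <- rbind(X, matrix(0, npad - n, ncol(X)))
  Fx <- mvfft(Xp)
  k <- seq_len(npad) - 1L
  omega <- ifelse(k <= npad / 2, 2 * pi * k, -2 * pi * (npad - k)) / (npad * dt)
  pos <- omega > 0
  lapply(scales, function(s) {
    psi <- numeric(npad)
    psi[pos] <- sqrt(2 * pi * s / dt) * pi^(-0.25) *
      exp(-(s * omega[pos] - MORLET_K0)^2 / 2)
    W <- mvfft(Fx * psi, inverse = TRUE) / npad
    W[seq_len(n), , drop = FALSE]
  })
}

#' Continuous wavelet transform (Morlet, k0 = 6)
#'
#' Computes the complex Morlet wavelet transform of a uniformly sampled weekly
#' series by frequency-domain convolution with zero padding to the next power
#' of two. Missing values are refused: impute first ([impute_missing()]).
#'
#' @param data data frame with `date` and a value column, or a numeric vector.
#' @param value value column name.
#' @param dt sampling interval in weeks (default 1).
#' @param scale_spec output of [scale_grid()]; default grid: 12 voices per
#'   octave from a period of `8*dt` up to half the record length.
#' @return object of class `wavelet_field`: list with `coef` (n x n_scales
#'   complex matrix), `scales`, `periods`, `dt`, `coi` (per-time trustworthy
#'   period, [cone_of_influence()]), `dates`, `series_name`.
#' @examples
#' x <- cos(2 * pi * (1:520) / 52)
#' f <- cwt(x)
#' @export
cwt <- function(data, value = "value", dt = 1, scale_spec = NULL) {
  v <- series_values(data, value, require_complete = TRUE)
  n <- length(v)
  if (is.null(scale_spec)) scale_spec <- scale_grid(n = n, dt = dt)
  if (n * dt < 2 * min(scale_spec$scales)) {
    abort("series shorter than twice the smallest scale")
  }
  W <- cwt_engine(matrix(v, ncol = 1), dt, scale_spec$scales)
  coef <- vapply(W, function(m) m[, 1], complex(n))
  structure(
    list(coef = coef, scales = scale_spec$scales, periods = scale_spec$periods,
         dj = scale_spec$dj, dt = dt, coi = cone_of_influence(n, dt),
         dates = series_dates(data, n),
         series_name = if (is.data.frame(data)) attr(data, "series_name") else NULL),
    class = "wavelet_field"
  )
}

#' @export
print.wavelet_field <- function(x, ...) {
  cat(sprintf("<wavelet_field> %d times x %d scales, periods %.1f..%.1f (dt = %g)\n",
              nrow(x$coef), ncol(x$coef), min(x$periods), max(x$periods), x$dt))
  invisible(x)
}

#' Local wavelet power spectrum
#'
#' Elementwise squared magnitude of the wavelet coefficients.
#'
#' @param field a `wavelet_field` from [cwt()], or a complex matrix.
#' @return real matrix (time x scale) of power, >= 0.
#' @export
wavelet_power <- function(field) {
  m <- if (inherits(field, "wavelet_field")) field$coef else field
  Re(m * Conj(m))
}

#' Wavelet cross-spectrum
#'
#' Elementwise product of the first transform with the complex conjugate of
#' the second, `w_x * Conj(w_y)`. `cross_spectrum(f, f)` equals the power of
#' `f` exactly; swapping the arguments conjugates the result.
#'
#' @param fx,fy `wavelet_field`s on identical time and scale axes.
#' @return complex matrix (time x scale).
#' @export
cross_spectrum <- function(fx, fy) {
  if (!identical(dim(fx$coef), dim(fy$coef)) ||
      !isTRUE(all.equal(fx$scales, fy$scales)) || fx$dt != fy$dt) {
    abort("wavelet fields have mismatching time/scale axes")
  }
  fx$coef * Conj(fy$coef)
}

#' Phase angle of a (smoothed) cross-spectrum
#'
#' Four-quadrant arctangent of the imaginary over the real part, in degrees in
#' (-180, 180]. Cells with zero modulus have undefined phase and are returned
#' as `NA`. This is the raw cross-spectrum angle; the lead/lag sign convention
#' of [wavelet_coherence()] (positive = first series lags the second) is
#' applied there by conjugating the smoothed cross-spectrum before calling
#' this function.
#'
#' @param z complex matrix or vector.
#' @return numeric array of angles in degrees, same shape as `z`.
#' @export
phase_angle <- function(z) {
  out <- atan2(Im(z), Re(z)) * 180 / pi
  out[Mod(z) == 0] <- NA_real_
  out[!is.na(out) & out <= -180] <- 180
  out
}

# --- smoothing operator ------------------------------------------------------

# Gaussian time kernel at scale s: weights exp(-u^2 / (2 (s/dt)^2)) truncated
# at |u| <= min(ceil(3 s/dt), n-1) samples, renormalized per time step over the
# in-record support (exact unit DC gain, constants preserved, also at edges).
time_kernel_halfwidth <- function(s, dt, n) min(ceiling(3 * s / dt), n - 1L)

time_kernel <- function(s, dt, h) exp(-((0:h)^2) / (2 * (s / dt)^2))

# Smooth each column of M (n x J, one column per scale) in time.
smooth_time <- function(M, scales, dt) {
  n <- nrow(M)
  out <- M
  for (j in seq_len(ncol(M))) {
    h <- time_kernel_halfwidth(scales[j], dt, n)
    kh <- time_kernel(scales[j], dt, h) # kh[1] is the center weight
    L <- 2^ceiling(log2(n + 2 * h + 1))
    kvec <- numeric(L)
    kvec[1:(h + 1)] <- kh
    if (h > 0) kvec[(L - h + 1):L] <- kh[(h + 1):2]
    kf <- fft(kvec)
    vp <- c(M[, j], rep(0, L - n))
    sm <- fft(fft(vp) * kf, inverse = TRUE)[seq_len(n)] / L
    if (is.double(M)) sm <- Re(sm)
    csum <- cumsum(kh)
    tt <- seq_len(n)
    mass <- csum[1 + pmin(h, tt - 1L)] + csum[1 + pmin(h, n - tt)] - kh[1]
    out[, j] <- sm / mass
  }
  out
}

# Boxcar across scales (columns), ~0.6 octaves wide, renormalized at the ends.
scale_smooth_halfwidth <- function(dj) max(0L, floor(0.3 / dj))

smooth_scales <- function(M, hw) {
  if (hw == 0L || ncol(M) == 1L) return(M)
  J <- ncol(M)
  acc <- M * 0
  cnt <- numeric(J)
  for (o in -hw:hw) {
    src <- pmin(pmax(seq_len(J) + o, 1L), J)
    valid <- seq_len(J) + o >= 1L & seq_len(J) + o <= J
    acc[, valid] <- acc[, valid] + M[, src[valid], drop = FALSE]
    cnt <- cnt + as.numeric(valid)
  }
  sweep(acc, 2, cnt, "/")
}

#' Smooth a time-scale field
#'
#' The smoothing operator of the coherence estimator: per scale, time
#' smoothing with a Gaussian kernel matched to the Morlet envelope (standard
#' deviation equal to the scale, truncated at three standard deviations,
#' renormalized over the in-record support); then a boxcar across scales of
#' about 0.6 octaves. Linear, preserves constant fields exactly (unit DC gain
#' in both directions, including at the edges).
#'
#' @param M numeric or complex matrix, time x scale.
#' @param scales scale vector (one per column of `M`).
#' @param dt sampling interval.
#' @param dj scale resolution in octaves (e.g. 1/12); controls the width of
#'   the cross-scale boxcar.
#' @return matrix of the same shape and mode as `M`.
#' @export
smooth_field <- function(M, scales, dt = 1, dj = 1 / 12) {
  M <- as.matrix(M)
  if (ncol(M) != length(scales)) abort("ncol(M) must equal length(scales)")
  smooth_scales(smooth_time(M, scales, dt), scale_smooth_halfwidth(dj))
}

# --- coherence ---------------------------------------------------------------

# Core coherence computation on two numeric vectors. Returns the smoothed
# spectra as well, for reuse by the significance machinery.
coherence_core <- function(xv, yv, dt, scale_spec) {
  n <- length(xv)
  W <- cwt_engine(cbind(xv, yv), dt, scale_spec$scales)
  J <- length(scale_spec$scales)
  Wx <- vapply(W, function(m) m[, 1], complex(n))
  Wy <- vapply(W, function(m) m[, 2], complex(n))
  inv_s <- 1 / scale_spec$scales
  Px <- sweep(Re(Wx * Conj(Wx)), 2, inv_s, "*")
  Py <- sweep(Re(Wy * Conj(Wy)), 2, inv_s, "*")
  Cxy <- sweep(Wx * Conj(Wy), 2, inv_s, "*")
  hw <- scale_smooth_halfwidth(scale_spec$dj)
  sPx <- smooth_scales(smooth_time(Px, scale_spec$scales, dt), hw)
  sPy <- smooth_scales(smooth_time(Py, scale_spec$scales, dt), hw)
  sC <- smooth_scales(smooth_time(Cxy, scale_spec$scales, dt), hw)
  coh <- Mod(sC)^2 / (sPx * sPy)
  list(coherence = coh, sm_cross = sC, sPx = sPx, sPy = sPy)
}

#' Wavelet coherence and phase between two weekly series
#'
#' Time- and scale-localised squared correlation between two series,
#' `wc = |<c_xy/s>|^2 / (<s_x/s> <s_y/s>)` where `< >` is the smoothing
#' operator of [smooth_field()] and `c_xy` the Morlet cross-spectrum. Values
#' lie in `[0, 1]` (1 = perfectly correlated at that time and period); any
#' numerical overshoot is clipped and counted. The phase angle encodes the
#' lead/lag: **positive phase means the first series lags the second** at that
#' period (so with `x` = phenology and `y` = a climate driver, positive angles
#' mean the biology lags the climate). The coherence value itself is
#' independent of the time shift between the series.
#'
#' @param data data frame holding both series as columns (plus `date`), or a
#'   numeric vector (then `y` must be a numeric vector too).
#' @param x,y column names (bare or quoted) when `data` is a data frame.
#' @param dt sampling interval in weeks.
#' @param scale_spec [scale_grid()] output; default 12 voices/octave, periods
#'   from 8 weeks to half the record.
#' @return object of class `wavelet_coherence`: `coherence`, `phase_deg` (both
#'   time x scale), `periods`, `scales`, `coi`, `inside_coi`, `dt`, `dates`,
#'   `n_clipped`, and (after [coherence_significance()]) `significant`,
#'   `alpha`, `null_quantile`. Use [tidy()] for a long tibble.
#' @export
wavelet_coherence <- function(data, x, y, dt = 1, scale_spec = NULL) {
  if (is.data.frame(data)) {
    xn <- as_name(enquo(x)); yn <- as_name(enquo(y))
    xv <- series_values(data, xn, require_complete = TRUE, what = xn)
    yv <- series_values(data, yn, require_complete = TRUE, what = yn)
    dates <- series_dates(data)
    pair <- c(xn, yn)
  } else {
    xv <- as.numeric(data); yv <- as.numeric(x)
    if (anyNA(xv) || anyNA(yv)) abort("series contain missing values; impute first")
    dates <- series_dates(NULL, length(xv))
    pair <- c("x", "y")
  }
  if (length(xv) != length(yv)) abort("series lengths differ")
  if (sd(xv) == 0 || sd(yv) == 0) abort("degenerate series: zero variance")
  n <- length(xv)
  if (is.null(scale_spec)) scale_spec <- scale_grid(n = n, dt = dt)
  core <- coherence_core(xv, yv, dt, scale_spec)
  coh <- core$coherence
  n_clip <- sum(coh > 1 + 1e-6 | coh < -1e-6, na.rm = TRUE)
  if (n_clip > 0) inform(sprintf("coherence: clipped %d cells to [0, 1]", n_clip))
  coh <- pmin(pmax(coh, 0), 1)
  # positive phase = first series lags the second
  phase <- phase_angle(Conj(core$sm_cross))
  coi <- cone_of_influence(n, dt)
  inside <- outer(coi, scale_spec$periods, `>=`)
  structure(
    list(coherence = coh, phase_deg = phase, sm_cross = core$sm_cross,
         scales = scale_spec$scales, periods = scale_spec$periods,
         dj = scale_spec$dj, dt = dt, coi = coi, inside_coi = inside,
         dates = dates, pair = pair, n_clipped = n_clip,
         significant = NULL, alpha = NULL, null_quantile = NULL),
    class = "wavelet_coherence"
  )
}

#' @export
print.wavelet_coherence <- function(x, ...) {
  cat(sprintf(
    "<wavelet_coherence> %s ~ %s: %d times x %d periods (%.1f..%.1f weeks)\n",
    x$pair[1], x$pair[2], nrow(x$coherence), ncol(x$coherence),
    min(x$periods), max(x$periods)))
  if (!is.null(x$significant)) {
    cat(sprintf("  significance: alpha = %g, %.1f%% of in-COI cells significant\n",
                x$alpha, 100 * mean(x$significant[x$inside_coi])))
  }
  invisible(x)
}

#' Global (time-averaged) wavelet spectrum
#'
#' Mean wavelet power per scale over the times inside the cone of influence.
#' With the transform's normalisation, white noise yields an approximately
#' flat global spectrum; `normalize = "scale"` additionally divides by scale
#' (the bias-rectified variant that makes equal-amplitude sinusoids at
#' different periods peak equally).
#'
#' @param field a `wavelet_field` from [cwt()].
#' @param normalize `"none"` (default) or `"scale"`.
#' @return tibble with `scale`, `period`, `power`, `n_cells`.
#' @export
global_spectrum <- function(field, normalize = c("none", "scale")) {
  normalize <- match.arg(normalize)
  pw <- wavelet_power(field)
  inside <- outer(field$coi, field$periods, `>=`)
  pw[!inside] <- NA
  gp <- colMeans(pw, na.rm = TRUE)
  if (normalize == "scale") gp <- gp / field$scales
  tibble(scale = field$scales, period = field$periods,
         power = as.numeric(gp), n_cells = colSums(inside))
}
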