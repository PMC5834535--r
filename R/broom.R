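# broom-style accessors for the wavelet result objects.

#' Tidy a wavelet field into a long tibble
#'
#' @param x a `wavelet_field` from [cwt()].
#' @param ... unused.
#' @return tibble with `time`, `date`, `scale`, `period`, `power`,
#'   `inside_coi`.
#' @method tidy wavelet_field
#' @export
tidy.wavelet_field <- function(x, ...) {
  n <- nrow(x$coef); J <- ncol(x$coef)
  pw <- wavelet_power(x)
  tibble(
    time = rep(seq_len(n), J),
    date = rep(x$dates, J),
    scale = rep(x$scales, each = n),
    period = rep(x$periods, each = n),
    power = as.vector(pw),
    inside_coi = as.vector(outer(x$coi, x$periods, `>=`))
  )
}

#' Tidy a wavelet coherence result into a long tibble
#'
#' @param x a `wavelet_coherence`.
#' @param ... unused.
#' @return tibble with `time`, `date`, `period`, `coherence`, `phase_deg`,
#'   `inside_coi` and `significant` (`NA` when no significance test was run).
#' @method tidy wavelet_coherence
#' @export
tidy.wavelet_coherence <- function(x, ...) {
  n <- nrow(x$coherence); J <- ncol(x$coherence)
  tibble(
    time = rep(seq_len(n), J),
    date = rep(x$dates, J),
    period = rep(x$periods, each = n),
    coherence = as.vector(x$coherence),
    phase_deg = as.vector(x$phase_deg),
    inside_coi = as.vector(x$inside_coi),
    significant = if (is.null(x$significant)) NA else as.vector(x$significant)
  )
}

#' One-row summary of a wavelet coherence result
#'
#' @param x a `wavelet_coherence`.
#' @param ... unused.
#' @return tibble with the pair, grid size, mean in-COI coherence, the
#'   fraction of in-COI cells marked significant (`NA` without a test),
#'   `alpha` and the count of clipped cells.
#' @method glance wavelet_coherence
#' @export
glance.wavelet_coherence <- function(x, ...) {
  obj <- x
  tibble(
    x = obj$pair[1], y = obj$pair[2],
    n_times = nrow(obj$coherence), n_scales = ncol(obj$coherence),
    mean_coherence_coi = mean(obj$coherence[obj$inside_coi]),
    frac_significant_coi = if (is.null(obj$significant)) NA_real_
      else mean(obj$significant[obj$inside_coi]),
    alpha = obj$alpha %||% NA_real_,
    n_clipped = obj$n_clipped
  )
}

#' Circular summary of a phase sample
#'
#' @param x a `phase_sample` from [band_select()].
#' @param ... unused.
#' @return the one-row tibble of [circular_mean_sd()] plus the band limits and
#'   mean per-cell lag in weeks.
#' @method glance phase_sample
#' @export
glance.phase_sample <- function(x, ...) {
  band <- attr(x, "band")
  if (nrow(x) == 0L) {
    return(tibble(mean_deg = NA_real_, sd_deg = NA_real_, r = NA_real_,
                  n = 0L, n_eff = NA_real_,
                  period_min = band[1], period_max = band[2],
                  mean_lag_weeks = NA_real_))
  }
  mutate(circular_mean_sd(x),
         period_min = band[1], period_max = band[2],
         mean_lag_weeks = mean(angle_to_lag(x$angle_deg, x$period)))
}
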