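# Leaf area index from hemispherical-photograph gap fractions.

#' Leaf-area-index inversion parameters
#'
#' @param g leaf projection function value; 0.5 corresponds to a spherical
#'   leaf inclination distribution.
#' @param omega clumping index; 0.9 is typical for broadleaf forests.
#' @param zenith_limit maximum view zenith angle used (degrees); only the
#'   portion of the image directly at the zenith (default < 4.5 deg) enters
#'   the inversion, which minimises distortion and the zenith dependence of
#'   `g` and `omega` (treated as constants within the disk).
#' @return list of class `lai_params`.
#' @export
lai_params <- function(g = 0.5, omega = 0.9, zenith_limit = 4.5) {
  if (!(g > 0 && g <= 1)) abort("`g` must be in (0, 1]")
  if (!(omega > 0 && omega <= 1)) abort("`omega` must be in (0, 1]")
  if (zenith_limit <= 0) abort("`zenith_limit` must be > 0")
  structure(list(g = g, omega = omega, zenith_limit = zenith_limit),
            class = "lai_params")
}

#' Invert gap fraction to leaf area index
#'
#' Light-penetration model: `LAI = -log(P) * cos(theta) / (omega * g)` with
#' `P` the gap fraction at view zenith angle `theta` (natural logarithm).
#' `P = 1` gives LAI 0 exactly; `P = 0` implies infinite LAI and is an error
#' (flag saturated records upstream, see [gap_fraction_from_mask()]).
#'
#' @param data tibble with columns `gap_fraction` and optionally `theta_deg`
#'   (default 0, at-zenith), or a numeric vector of gap fractions.
#' @param params [lai_params()].
#' @param theta_deg zenith angle(s), used when `data` is a vector.
#' @return the input tibble with an `lai` column (or a numeric vector).
#' @export
lai_from_gap_fraction <- function(data, params = lai_params(), theta_deg = 0) {
  vec_in <- !is.data.frame(data)
  p <- if (vec_in) as.numeric(data) else data$gap_fraction
  th <- if (vec_in) theta_deg else (data$theta_deg %||% 0)
  if (any(p > 1, na.rm = TRUE)) abort("gap fraction > 1")
  if (any(p <= 0, na.rm = TRUE)) {
    abort("gap fraction = 0 implies infinite LAI; flag saturated records instead")
  }
  if (any(th >= params$zenith_limit, na.rm = TRUE)) {
    abort(sprintf("zenith angle beyond the %g deg limit", params$zenith_limit))
  }
  lai <- -log(p) * cos(th * pi / 180) / (params$omega * params$g)
  if (vec_in) return(lai)
  data$lai <- lai
  data
}

#' Gap fraction from a binary sky/vegetation mask
#'
#' `P` = sky pixels / total pixels within the zenith disk. An all-vegetation
#' disk (no sky pixel) has `P = 0` and infinite apparent LAI; such records get
#' `P` floored at half a pixel's fraction and are flagged `saturated = TRUE`
#' (excluded from aggregation by default downstream).
#'
#' @param mask logical or 0/1 matrix/vector restricted to the zenith disk;
#'   `TRUE`/1 = sky.
#' @param location,date optional identifiers copied to the output.
#' @return one-row tibble: `location`, `date`, `theta_deg` (0), `gap_fraction`,
#'   `saturated`.
#' @export
gap_fraction_from_mask <- function(mask, location = NA_character_, date = NA) {
  v <- as.logical(as.vector(as.matrix(mask)))
  v <- v[!is.na(v)]
  if (length(v) == 0L) abort("empty zenith disk: no classified pixels")
  p <- mean(v)
  saturated <- p == 0
  if (saturated) p <- 0.5 / length(v)
  tibble(location = location, date = date, theta_deg = 0,
         gap_fraction = p, saturated = saturated)
}

#' Aggregate per-location LAI to monthly means and standard errors
#'
#' Per calendar month: mean LAI across locations, standard error `sd/sqrt(n)`
#' and the number of contributing locations. One value per location-month is
#' assumed (multiple photos per location are combined upstream). Saturated
#' records (if a `saturated` column is present) are excluded by default.
#'
#' @param data tibble with `location`, `date`, `lai` (and optionally
#'   `saturated`).
#' @param drop_saturated exclude saturated records (default TRUE).
#' @return tibble of class `lai_monthly`: `month` (first day), `lai_mean`,
#'   `lai_se` (`NA` and flagged when a single location reports), `n`.
#' @export
aggregate_lai <- function(data, drop_saturated = TRUE) {
  stopifnot(all(c("date", "lai") %in% names(data)))
  if (drop_saturated && "saturated" %in% names(data)) {
    data <- filter(data, !.data$saturated)
  }
  out <- data |>
    mutate(month = lubridate::floor_date(as.Date(.data$date), "month")) |>
    group_by(.data$month) |>
    summarise(
      lai_mean = mean(.data$lai, na.rm = TRUE),
      lai_se = if (sum(!is.na(.data$lai)) > 1) {
        sd(.data$lai, na.rm = TRUE) / sqrt(sum(!is.na(.data$lai)))
      } else NA_real_,
      n = sum(!is.na(.data$lai)),
      .groups = "drop"
    ) |>
    mutate(se_undefined = .data$n < 2)
  class(out) <- c("lai_monthly", class(out))
  out
}

#' Histogram of median leaf life spans
#'
#' Bins species' median leaf life spans (months), optionally grouped by site
#' or stratum (e.g. canopy vs understory). Counts sum to the number of input
#' records.
#'
#' @param data tibble with `lifespan_months` (> 0) and optional grouping
#'   columns.
#' @param breaks bin edges in months (default 0, 6, 12, ..., up to the max).
#' @param group optional grouping column name.
#' @return tibble: grouping column (if any), `bin_lo`, `bin_hi`, `count`.
#' @export
lifespan_histogram <- function(data, breaks = NULL, group = NULL) {
  if (nrow(data) == 0L) {
    return(tibble(bin_lo = numeric(), bin_hi = numeric(), count = integer()))
  }
  if (any(data$lifespan_months <= 0, na.rm = TRUE)) {
    abort("non-positive leaf life span")
  }
  if (is.null(breaks)) {
    breaks <- seq(0, 6 * ceiling(max(data$lifespan_months, na.rm = TRUE) / 6), by = 6)
  }
  bin_one <- function(x) {
    b <- cut(x, breaks = breaks, right = TRUE, include.lowest = FALSE)
    tibble(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
           count = as.integer(table(b)))
  }
  if (is.null(group)) return(bin_one(data$lifespan_months))
  data |>
    group_by(.data[[group]]) |>
    dplyr::group_modify(~ bin_one(.x$lifespan_months)) |>
    ungroup()
}
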