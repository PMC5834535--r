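#' Seed equivalents per species and week
#'
#' Converts a long seed-trap census table into weekly seed-equivalent series:
#' for each species and week, the sum of mature seeds plus mature fruits
#' multiplied by the species mean number of seeds per fruit. Records flagged
#' immature or damaged never enter the sum. Counts are summed over traps
#' within a species-week before the conversion (the formula is linear, so the
#' result is additive over traps).
#'
#' @param data long census tibble with columns `species`, `date` (week start),
#'   `mature_seeds`, `mature_fruits` and optionally `immature`, `damaged`
#'   (ignored by construction) and `seeds_per_fruit`.
#' @param species_meta optional species metadata tibble with columns `species`
#'   and `seeds_per_fruit`, used when `data` lacks a `seeds_per_fruit` column.
#' @return tibble with columns `species`, `date`, `seeds` (seed equivalents).
#' @examples
#' x <- tibble::tibble(species = "sp1", date = as.Date("2000-01-03"),
#'                     mature_seeds = 3, mature_fruits = 2, seeds_per_fruit = 5)
#' seed_equivalents(x) # 3 + 2*5 = 13
#' @export
seed_equivalents <- function(data, species_meta = NULL) {
  if (!"seeds_per_fruit" %in% names(data)) {
    if (is.null(species_meta)) {
      abort("`seeds_per_fruit` not in data and no `species_meta` supplied")
    }
    data <- left_join(
      data, select(species_meta, "species", "seeds_per_fruit"),
      by = "species"
    )
  }
  agg <- data |>
    group_by(.data$species, .data$date) |>
    summarise(
      mature_seeds = sum(.data$mature_seeds, na.rm = TRUE),
      mature_fruits = sum(.data$mature_fruits, na.rm = TRUE),
      seeds_per_fruit = .data$seeds_per_fruit[1],
      .groups = "drop"
    )
  bad <- agg$mature_fruits > 0 & (is.na(agg$seeds_per_fruit) | agg$seeds_per_fruit <= 0)
  if (any(bad)) {
    abort(sprintf(
      "missing or non-positive seeds_per_fruit for species with fruits: %s",
      paste(unique(agg$species[bad]), collapse = ", ")
    ))
  }
  agg |>
    mutate(seeds = .data$mature_seeds +
             .data$mature_fruits * dplyr::coalesce(.data$seeds_per_fruit, 0)) |>
    select("species", "date", "seeds")
}

#' Filter species by census count and exclusion list
#'
#' Retains species recorded (any strictly positive value) in strictly more
#' than `min_censuses` weekly censuses, then drops species on the exclusion
#' list. The thresholds used in community analyses of this kind are 10
#' censuses for seed fall and 3 for leaf fall.
#'
#' @param data long tibble with `species`, `date` and one or more numeric
#'   record columns (e.g. `seeds` or `dry_mass`).
#' @param min_censuses retain species with more than this many nonzero-record
#'   censuses (strict inequality).
#' @param exclude character vector of species names to drop regardless of
#'   census count.
#' @param record_cols columns that define a "record"; default: all numeric
#'   columns other than `date`.
#' @return Filtered tibble; attributes `n_total` and `n_retained` report the
#'   species counts before and after filtering.
#' @export
filter_species <- function(data, min_censuses, exclude = character(),
                           record_cols = NULL) {
  if (min_censuses < 0) abort("`min_censuses` must be >= 0")
  if (is.null(record_cols)) {
    record_cols <- setdiff(
      names(data)[vapply(data, is.numeric, logical(1))], c("date")
    )
  }
  if (length(record_cols) == 0L) abort("no record columns found")
  rec <- rowSums(as.matrix(data[record_cols]), na.rm = TRUE) > 0
  censuses <- data |>
    mutate(.rec = rec) |>
    group_by(.data$species) |>
    summarise(n_censuses = dplyr::n_distinct(.data$date[.data$.rec]),
              .groups = "drop")
  keep <- censuses$species[censuses$n_censuses > min_censuses]
  keep <- setdiff(keep, exclude)
  out <- filter(data, .data$species %in% keep)
  n_total <- dplyr::n_distinct(data$species)
  inform(sprintf("filter_species: retained %d of %d species (> %d censuses%s)",
                 length(keep), n_total, min_censuses,
                 if (length(exclude)) sprintf(", %d excluded by name",
                                              sum(unique(data$species) %in% exclude))
                 else ""))
  attr(out, "n_total") <- n_total
  attr(out, "n_retained") <- length(keep)
  out
}

#' Community phenology series
#'
#' Averages normalised per-species weekly series into a single community
#' series: each species is z-scored over its full record (mean subtracted,
#' divided by standard deviation, missing weeks excluded from the moments),
#' then species are averaged without weights week by week. Weeks in which no
#' species reports are flagged missing. Species with zero variance carry no
#' phenological signal and are dropped with a warning.
#'
#' @param data long tibble with columns `species`, `date` and a value column.
#' @param value name of the value column (default: first numeric non-date
#'   column).
#' @return A [weekly_series()] tibble (`date`, `value`, plus `n_species`, the
#'   number of species contributing to each week).
#' @export
community_series <- function(data, value = NULL) {
  if (is.null(value)) {
    value <- setdiff(names(data)[vapply(data, is.numeric, logical(1))], "date")[1]
  }
  wide <- data |>
    select("species", "date", dplyr::all_of(value)) |>
    tidyr::pivot_wider(names_from = "species", values_from = dplyr::all_of(value)) |>
    arrange(.data$date)
  m <- as.matrix(wide[-1])
  mu <- colMeans(m, na.rm = TRUE)
  sg <- apply(m, 2, sd, na.rm = TRUE)
  flat <- is.na(sg) | sg == 0
  if (all(flat)) abort("all species series are constant; community series undefined")
  if (any(flat)) {
    warn(sprintf("dropping %d zero-variance species from community average", sum(flat)))
    m <- m[, !flat, drop = FALSE]
    mu <- mu[!flat]; sg <- sg[!flat]
  }
  z <- sweep(sweep(m, 2, mu, "-"), 2, sg, "/")
  n_sp <- rowSums(!is.na(z))
  val <- rowMeans(z, na.rm = TRUE)
  val[n_sp == 0] <- NA_real_
  out <- weekly_series(wide$date, val, name = "community")
  out$n_species <- n_sp
  out
}

#' Soil water deficit index from gravimetric samples
#'
#' Interpolates irregular (1-3 weekly) gravimetric soil water content samples
#' to a uniform weekly grid, then maps them to the deficit index
#' `(swc_max - swc) / (swc_max - swc_min)`, which approaches 0 in wet
#' conditions and 1 in dry conditions. By default the extremes are the
#' record-wide extrema of the interpolated weekly series.
#'
#' @param samples tibble with columns `date` (strictly increasing) and `swc`
#'   (> 0), at regular or irregular spacing.
#' @param swc_max,swc_min reference extremes; default record extrema.
#' @param weekly_dates optional target weekly grid; default: 7-day grid from
#'   the first sample date to the last.
#' @return [weekly_series()] of the deficit index in `[0, 1]` (values are
#'   clipped only if custom extremes are narrower than the record).
#' @export
soil_water_deficit <- function(samples, swc_max = NULL, swc_min = NULL,
                               weekly_dates = NULL) {
  if (!all(c("date", "swc") %in% names(samples))) {
    abort("`samples` needs columns `date` and `swc`")
  }
  samples <- arrange(samples, .data$date)
  if (any(diff(as.numeric(samples$date)) <= 0)) abort("sample dates must strictly increase")
  if (any(samples$swc <= 0, na.rm = TRUE)) abort("soil water content must be > 0")
  if (is.null(weekly_dates)) {
    weekly_dates <- seq(min(samples$date), max(samples$date), by = 7)
  }
  swc_w <- approx(as.numeric(samples$date), samples$swc,
                  xout = as.numeric(weekly_dates), rule = 2)$y
  if (is.null(swc_max)) swc_max <- max(swc_w, na.rm = TRUE)
  if (is.null(swc_min)) swc_min <- min(swc_w, na.rm = TRUE)
  if (swc_max == swc_min) abort("degenerate range: swc_max == swc_min")
  idx <- (swc_max - swc_w) / (swc_max - swc_min)
  idx <- pmin(pmax(idx, 0), 1)
  weekly_series(weekly_dates, idx, name = "soil_water_deficit", units = "index 0-1")
}

# Magnus-type saturation vapour pressure over water, kPa.
# Constants: Alduchov & Eskridge (1996) improved Magnus form.
esat_kpa <- function(temp_c) {
  0.61094 * exp(17.625 * temp_c / (temp_c + 243.04))
}

#' Midday vapour pressure deficit, aggregated weekly
#'
#' Computes VPD from sub-daily temperature and relative humidity, keeping only
#' records in the central part of the day (10:00 to 17:00 local time) when the
#' influence on photosynthesis and stomatal control is largest, then averages
#' to weekly values. Saturation vapour pressure uses a Magnus-type formula
#' (`0.61094 * exp(17.625 T / (T + 243.04))` kPa); VPD = e_sat(T) (1 - RH/100).
#'
#' @param data tibble with columns `timestamp` (POSIXct), `temperature` (deg
#'   C) and `rh` (percent, 0-100).
#' @param week_anchor `Date` that anchors the weekly bins; default: the date
#'   of the first timestamp.
#' @param hours half-open local-time window `[from, to)` of retained records.
#' @return [weekly_series()] of weekly mean midday VPD (kPa); weeks with no
#'   in-window records are `NA`.
#' @export
midday_vpd <- function(data, week_anchor = NULL, hours = c(10, 17)) {
  if (any(data$rh < 0 | data$rh > 100, na.rm = TRUE)) {
    abort("relative humidity outside [0, 100]")
  }
  hr <- lubridate::hour(data$timestamp) + lubridate::minute(data$timestamp) / 60
  mid <- data[hr >= hours[1] & hr < hours[2], , drop = FALSE]
  dts <- as.Date(data$timestamp)
  if (is.null(week_anchor)) week_anchor <- min(dts)
  all_weeks <- week_anchor + 7 * (0:((as.numeric(max(dts) - week_anchor)) %/% 7))
  if (nrow(mid) == 0L) {
    return(weekly_series(all_weeks, rep(NA_real_, length(all_weeks)),
                         name = "vpd", units = "kPa"))
  }
  mid$vpd <- esat_kpa(mid$temperature) * (1 - mid$rh / 100)
  mid$week <- week_anchor + 7 * (as.numeric(as.Date(mid$timestamp) - week_anchor) %/% 7)
  wk <- mid |>
    group_by(.data$week) |>
    summarise(value = mean(.data$vpd, na.rm = TRUE), .groups = "drop")
  out <- tibble(date = all_weeks) |>
    left_join(rename(wk, date = "week"), by = "date")
  weekly_series(out$date, out$value, name = "vpd", units = "kPa")
}

#' Weekly VPD from weekly mean temperature and relative humidity
#'
#' Convenience for climate tables already aggregated to weekly resolution
#' (e.g. synthetic fixtures): applies the same Magnus-type formula as
#' [midday_vpd()] directly to the weekly means.
#'
#' @param temperature weekly mean temperature (deg C).
#' @param rh weekly mean relative humidity (percent).
#' @return numeric vector of VPD (kPa).
#' @export
vpd_from_weekly <- function(temperature, rh) {
  if (any(rh < 0 | rh > 100, na.rm = TRUE)) abort("relative humidity outside [0, 100]")
  esat_kpa(temperature) * (1 - rh / 100)
}

#' Seasonal detrending by week-of-year climatology
#'
#' Subtracts the week-of-year climatological mean and rescales the residual to
#' zero mean and unit variance. Weeks are indexed 1..53 counting 7-day blocks
#' from January 1 of each calendar year (day-of-year %/% 7 + 1); the 53rd
#' partial week forms its own (small) climatology group. This anomaly form is
#' used for display only; the wavelet analyses consume non-detrended series.
#'
#' @param data data frame with `date` and a value column.
#' @param value value column name.
#' @param scale rescale the residual to unit variance (default `TRUE`); with
#'   `FALSE` the raw climatology residual is returned (a purely
#'   annual-periodic input then comes back as approximately zero).
#' @return [weekly_series()] of standardized anomalies.
#' @export
seasonal_detrend <- function(data, value = "value", scale = TRUE) {
  v <- series_values(data, value)
  d <- as.Date(data$date)
  if (as.numeric(max(d) - min(d)) < 2 * 364) {
    abort("seasonal_detrend needs at least 2 full years of data")
  }
  woy <- pmin(lubridate::yday(d) %/% 7L + 1L, 53L)
  clim <- tapply(v, woy, mean, na.rm = TRUE)
  anom <- v - as.numeric(clim[as.character(woy)])
  if (scale) {
    s <- sd(anom, na.rm = TRUE)
    if (is.na(s) || s == 0) s <- 1
    anom <- (anom - mean(anom, na.rm = TRUE)) / s
  }
  weekly_series(d, anom, name = "anomaly",
                units = if (scale) "sd units" else attr(data, "units"))
}

#' Centered running mean
#'
#' Centered moving average with the ends flagged missing where the window is
#' incomplete. The default 13-week window approximates the 3-month running
#' means drawn over weekly anomaly series.
#'
#' @param data data frame with `date` and a value column, or a numeric vector.
#' @param window_weeks window length in weeks (odd recommended).
#' @param value value column name.
#' @return same shape as the input with the value column smoothed.
#' @export
running_mean <- function(data, window_weeks = 13, value = "value") {
  if (window_weeks < 1) abort("`window_weeks` must be >= 1")
  vec_in <- !is.data.frame(data)
  v <- if (vec_in) as.numeric(data) else data[[value]]
  if (window_weeks > length(v)) abort("window longer than series")
  sm <- as.numeric(stats::filter(v, rep(1 / window_weeks, window_weeks), sides = 2))
  if (vec_in) return(sm)
  data[[value]] <- sm
  data
}

#' Identify ENSO events from a monthly ONI-style index
#'
#' Finds maximal runs of at least `min_months` consecutive months with the
#' index strictly above `threshold` (warm events, El Nino) or strictly below
#' `-threshold` (cold events, La Nina). The conventional rule is index values
#' > 0.5 degC or < -0.5 degC for at least five consecutive months; a month at
#' exactly the threshold never qualifies.
#'
#' @param data tibble with columns `date` (first day of month) and `oni`
#'   (deg C), at uniform monthly spacing.
#' @param threshold qualifying absolute index value (strict), default 0.5.
#' @param min_months minimum run length, default 5.
#' @return tibble with one row per event: `start`, `end` (month dates,
#'   inclusive), `sign` ("warm"/"cold"), `months`, `peak` (signed extreme).
#' @export
identify_enso_events <- function(data, threshold = 0.5, min_months = 5) {
  stopifnot(all(c("date", "oni") %in% names(data)))
  data <- arrange(data, .data$date)
  x <- data$oni
  state <- ifelse(is.na(x), 0L, ifelse(x > threshold, 1L, ifelse(x < -threshold, -1L, 0L)))
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0L & r$lengths >= min_months
  if (!any(keep)) {
    return(tibble(start = as.Date(character()), end = as.Date(character()),
                  sign = character(), months = integer(), peak = numeric()))
  }
  tibble(
    start = data$date[starts[keep]],
    end = data$date[ends[keep]],
    sign = ifelse(r$values[keep] > 0, "warm", "cold"),
    months = r$lengths[keep],
    peak = purrr::map2_dbl(starts[keep], ends[keep], function(a, b) {
      seg <- x[a:b]
      seg[which.max(abs(seg))]
    })
  )
}

#' Rescale a series to the unit interval
#'
#' `(x - min) / (max - min)`, the normalisation used to overlay variables with
#' different units on a common 0-1 axis.
#'
#' @param data data frame with a value column, or numeric vector.
#' @param value value column name.
#' @return same shape as the input, values in `[0, 1]`.
#' @export
normalize_01 <- function(data, value = "value") {
  vec_in <- !is.data.frame(data)
  v <- if (vec_in) as.numeric(data) else data[[value]]
  rng <- range(v, na.rm = TRUE)
  if (diff(rng) == 0) abort("degenerate range: constant series cannot be normalized to 0-1")
  out <- (v - rng[1]) / (rng[2] - rng[1])
  if (vec_in) return(out)
  data[[value]] <- out
  data
}
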