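#' Construct a weekly series tibble
#'
#' The package's elementary time-series container is an ordinary tibble with a
#' `date` column at uniform 7-day spacing and a `value` column. Missing weeks
#' are carried as explicit `NA` values, never dropped. `weekly_series()` builds
#' and validates one; most functions in the package accept any data frame with
#' these two columns.
#'
#' @param date vector of `Date`s at 7-day spacing (or a single start date when
#'   `value` supplies the length).
#' @param value numeric values, one per week; `NA` marks a missing week.
#' @param name identifier stored as the `series_name` attribute.
#' @param units free-text units stored as the `units` attribute.
#' @return A tibble with columns `date`, `value` and class `weekly_series`.
#' @examples
#' ws <- weekly_series(as.Date("2000-01-03"), rnorm(52), name = "demo")
#' @export
weekly_series <- function(date, value, name = NULL, units = NULL) {
  if (length(date) == 1L && length(value) > 1L) {
    date <- as.Date(date) + 7 * (seq_along(value) - 1L)
  }
  date <- as.Date(date)
  out <- tibble(date = date, value = as.numeric(value))
  validate_weekly(out)
  out <- arrange(out, .data$date)
  attr(out, "series_name") <- name
  attr(out, "units") <- units
  class(out) <- c("weekly_series", class(out))
  out
}

validate_weekly <- function(data, what = "series") {
  if (!all(c("date", "value") %in% names(data))) {
    abort(sprintf("%s must have `date` and `value` columns", what))
  }
  d <- sort(as.Date(data$date))
  if (length(d) > 1L) {
    sp <- as.numeric(diff(d))
    if (any(sp != 7)) {
      abort(sprintf("%s is not uniformly weekly: spacing other than 7 days found", what))
    }
  }
  invisible(data)
}

#' @export
print.weekly_series <- function(x, ...) {
  nm <- attr(x, "series_name")
  un <- attr(x, "units")
  cat(sprintf(
    "<weekly_series%s> %d weeks, %s .. %s%s, %d missing\n",
    if (is.null(nm)) "" else paste0(": ", nm),
    nrow(x), min(x$date), max(x$date),
    if (is.null(un)) "" else paste0(" [", un, "]"),
    sum(is.na(x$value))
  ))
  NextMethod()
}

# Extract a numeric value vector (and check for missingness when required).
series_values <- function(data, value = "value", require_complete = FALSE,
                          what = "series") {
  v <- if (is.data.frame(data)) data[[value]] else as.numeric(data)
  if (is.null(v)) abort(sprintf("column `%s` not found in %s", value, what))
  if (require_complete && anyNA(v)) {
    abort(paste0(
      what, " contains missing values; the wavelet transform requires a ",
      "complete series. Impute first (see `impute_missing()`)."
    ))
  }
  as.numeric(v)
}

series_dates <- function(data, n = NULL) {
  if (is.data.frame(data) && "date" %in% names(data)) return(as.Date(data$date))
  if (is.null(n)) n <- if (is.data.frame(data)) nrow(data) else length(data)
  as.Date("2000-01-03") + 7 * (seq_len(n) - 1L)
}

#' Fill missing weeks by linear interpolation
#'
#' Simple documented imputation used before wavelet analysis, which refuses
#' `NA` values. Interior gaps are linearly interpolated in time; leading or
#' trailing missing weeks are filled with the nearest observed value.
#'
#' @param data data frame with `date` and a value column.
#' @param value name of the value column (default `"value"`).
#' @return The input with the value column imputed and a logical
#'   `imputed` column marking filled weeks.
#' @export
impute_missing <- function(data, value = "value") {
  v <- data[[value]]
  if (!anyNA(v)) {
    data$imputed <- FALSE
    return(data)
  }
  ok <- !is.na(v)
  if (sum(ok) < 2L) abort("cannot impute: fewer than 2 observed values")
  idx <- seq_along(v)
  filled <- approx(idx[ok], v[ok], xout = idx, rule = 2)$y
  data[[value]] <- filled
  data$imputed <- !ok
  data
}
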