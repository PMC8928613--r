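#' Construct a daily time series
#'
#' A `daily_series` is a regularly sampled, gap-free daily time series with
#' calendar anchoring. It is the common currency of the package: observed
#' concentrations, model predictions, log-scale signals and daily health
#' counts are all carried in this form. Gap handling (interpolation, run
#' extraction) happens upstream in the preprocessing functions; a
#' `daily_series` itself must be complete and finite.
#'
#' @param values Numeric vector of daily values (concentration in ug/m3,
#'   log-concentration, or counts). Must be finite, length >= 2, no missing.
#' @param start_date A `Date` (or string coercible to one) for the first day.
#' @param days_per_year Days per calendar year used to convert Fourier
#'   indices to cycles per year. Default 365, which makes integer
#'   cycles-per-year frequencies exact on an n = 1095 (3-year) grid;
#'   set 365.25 for long real-data spans that include leap days.
#'
#' @return An object of class `daily_series`: a numeric vector with
#'   attributes `start_date` and `days_per_year`.
#' @examples
#' z <- daily_series(rnorm(730, 10, 2), start_date = "2010-01-01")
#' length(z)
#' @export
daily_series <- function(values, start_date = as.Date("2000-01-01"),
                         days_per_year = 365) {
  values <- as.numeric(values)
  if (length(values) < 2L) {
    stop("a daily series needs at least 2 days, got ", length(values))
  }
  if (anyNA(values) || !all(is.finite(values))) {
    stop("daily series values must be finite with no missing entries")
  }
  if (!is.numeric(days_per_year) || length(days_per_year) != 1L ||
      !is.finite(days_per_year) || days_per_year <= 0) {
    stop("'days_per_year' must be a single positive number")
  }
  structure(values,
            start_date = as.Date(start_date),
            days_per_year = days_per_year,
            class = "daily_series")
}

#' @export
print.daily_series <- function(x, ...) {
  cat(sprintf("<daily_series> %d days from %s (days_per_year = %g)\n",
              length(x), format(attr(x, "start_date")), attr(x, "days_per_year")))
  cat(sprintf("  mean %.4g, sd %.4g, range [%.4g, %.4g]\n",
              mean(x), stats::sd(x), min(x), max(x)))
  invisible(x)
}

#' @export
#' @rdname daily_series
is_daily_series <- function(x) inherits(x, "daily_series")

#' Dates covered by a daily series
#' @param x A `daily_series`.
#' @return A `Date` vector of length `length(x)`.
#' @export
series_dates <- function(x) {
  stopifnot(is_daily_series(x))
  attr(x, "start_date") + seq_along(x) - 1L
}

# strip class/attributes; plain numeric for internal math
series_values <- function(x) as.numeric(unclass(x))

# rebuild a series with the same calendar anchoring as `template`
series_like <- function(values, template) {
  daily_series(values,
               start_date = attr(template, "start_date"),
               days_per_year = attr(template, "days_per_year"))
}

check_same_length <- function(a, b, what = c("obs", "pred")) {
  if (length(a) != length(b)) {
    stop(sprintf("'%s' (%d days) and '%s' (%d days) must have equal length",
                 what[1], length(a), what[2], length(b)))
  }
  invisible(TRUE)
}
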