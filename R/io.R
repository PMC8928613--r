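#' Read a raw monitor series from CSV
#'
#' Reads a CSV with a date column and a numeric value column into a
#' `raw_series`: a date-indexed record that may contain gaps (missing
#' dates, or dates with an empty value cell). Dates must be unique;
#' the records are sorted and missing calendar days inside the covered
#' range are represented explicitly as `NA` values so that gap lengths are
#' well defined.
#'
#' @param path CSV file path.
#' @param date_col,value_col Column names (defaults `"date"`, `"value"`).
#' @param site_id Optional monitor/site identifier carried in the result.
#' @return An object of class `raw_series`: a data frame with `date`
#'   (`Date`) and `value` (numeric, `NA` at gaps), with attribute
#'   `site_id`.
#' @export
read_series <- function(path, date_col = "date", value_col = "value",
                        site_id = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c(date_col, value_col)) {
    if (!col %in% names(df)) {
      stop(sprintf("column '%s' not found in %s", col, path))
    }
  }
  dates <- tryCatch(as.Date(df[[date_col]]), error = function(e) NULL)
  if (is.null(dates) || anyNA(dates)) {
    if (is.null(dates)) {
      parsed <- vapply(as.character(df[[date_col]]), function(s) {
        tryCatch(!is.na(as.Date(s)), error = function(e) FALSE)
      }, logical(1))
    } else {
      parsed <- !is.na(dates)
    }
    stop(sprintf("unparseable date at row %d of %s", which(!parsed)[1], path))
  }
  raw_vals <- df[[value_col]]
  values <- suppressWarnings(as.numeric(raw_vals))
  bad <- !is.na(raw_vals) & trimws(as.character(raw_vals)) != "" & is.na(values)
  if (any(bad)) {
    stop(sprintf("non-numeric value '%s' at row %d of %s",
                 raw_vals[which(bad)[1]], which(bad)[1], path))
  }
  if (anyDuplicated(dates)) {
    stop(sprintf("duplicated date %s in %s",
                 format(dates[duplicated(dates)][1]), path))
  }
  ord <- order(dates)
  dates <- dates[ord]
  values <- values[ord]
  full <- seq(min(dates), max(dates), by = "day")
  out <- data.frame(date = full, value = NA_real_)
  out$value[match(dates, full)] <- values
  structure(out, site_id = site_id, class = c("raw_series", "data.frame"))
}

new_raw_series <- function(date, value, site_id = NULL) {
  structure(data.frame(date = as.Date(date), value = as.numeric(value)),
            site_id = site_id, class = c("raw_series", "data.frame"))
}

#' Write a daily series (or counts) as CSV
#'
#' Values are written with full decimal precision (17 significant digits)
#' so a write/read round trip reproduces them exactly.
#'
#' @param x A `daily_series`.
#' @param path Output CSV path.
#' @param value_col Name for the value column (default `"value"`).
#' @return Invisibly, `path`.
#' @export
write_series <- function(x, path, value_col = "value") {
  stopifnot(is_daily_series(x))
  df <- data.frame(date = format(series_dates(x)),
                   value = sprintf("%.17g", series_values(x)))
  names(df)[2] <- value_col
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fill short gaps in a raw monitor series by linear interpolation
#'
#' Runs of consecutive missing days strictly shorter than `max_gap` days
#' are filled by linear interpolation between the flanking observed
#' values; longer runs, and gaps at the series boundary (no flanking value
#' on one side), are left missing.
#'
#' @param raw A `raw_series`.
#' @param max_gap Gap threshold in days (default 10: gaps of 1-9 missing
#'   days are filled).
#' @return A `raw_series` with short gaps filled.
#' @export
interpolate_short_gaps <- function(raw, max_gap = 10) {
  stopifnot(inherits(raw, "raw_series"))
  v <- raw$value
  n <- length(v)
  miss <- is.na(v)
  if (!any(miss)) return(raw)
  r <- rle(miss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (g in which(r$values)) {
    len <- r$lengths[g]
    lo <- starts[g] - 1L
    hi <- ends[g] + 1L
    if (len < max_gap && lo >= 1L && hi <= n) {
      v[starts[g]:ends[g]] <- v[lo] +
        (v[hi] - v[lo]) * (seq_len(len)) / (len + 1)
    }
  }
  out <- raw
  out$value <- v
  out
}

#' Extract the longest complete run as a daily series
#'
#' Returns the longest contiguous stretch with no missing values, as a
#' `daily_series` anchored at the run's first date. Ties are broken toward
#' the earliest run. Monitors whose longest run is shorter than `min_days`
#' (default 365, one year of daily data) are rejected.
#'
#' @param raw A `raw_series` (usually after [interpolate_short_gaps()]).
#' @param min_days Minimum acceptable run length (default 365).
#' @param days_per_year Passed to [daily_series()] (default 365).
#' @return A `daily_series`.
#' @export
longest_complete_run <- function(raw, min_days = 365, days_per_year = 365) {
  stopifnot(inherits(raw, "raw_series"))
  miss <- is.na(raw$value)
  r <- rle(miss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(!r$values)
  if (length(ok) == 0L) stop("series has no observed values")
  best <- ok[which.max(r$lengths[ok])]  # which.max takes the earliest tie
  len <- r$lengths[best]
  if (len < min_days) {
    stop(sprintf("longest complete run is %d days, below the %d-day minimum",
                 len, min_days))
  }
  idx <- starts[best]:ends[best]
  daily_series(raw$value[idx], start_date = raw$date[idx[1]],
               days_per_year = days_per_year)
}

#' Evaluate a prediction CSV against an observation CSV
#'
#' Reads both series, restricts them to their common date range (after
#' short-gap interpolation and longest-complete-run extraction of the
#' intersection), computes overall and per-band performance metrics, and
#' optionally writes them as CSV. This is the programmatic core of the
#' `evaluate` command-line subcommand.
#'
#' @param observed_csv,predicted_csv CSV paths (columns date, value).
#' @param spec A [band_spec()], or a path to a YAML band config.
#' @param output Optional path for the metrics CSV.
#' @param max_gap,min_days Preprocessing parameters (see
#'   [interpolate_short_gaps()] and [longest_complete_run()]).
#' @param days_per_year Days per year for the frequency grid.
#' @param verbose Log trimming information to stderr?
#' @return Invisibly, the metrics data frame.
#' @export
evaluate_files <- function(observed_csv, predicted_csv,
                           spec = default_band_spec(), output = NULL,
                           max_gap = 10, min_days = 365,
                           days_per_year = 365, verbose = FALSE) {
  if (is.character(spec)) spec <- read_band_spec(spec)
  obs <- interpolate_short_gaps(read_series(observed_csv), max_gap)
  pred <- interpolate_short_gaps(read_series(predicted_csv), max_gap)
  common <- intersect(obs$date, pred$date)
  if (length(common) == 0L) stop("observed and predicted series share no dates")
  common <- as.Date(common, origin = "1970-01-01")
  keep_o <- obs$date %in% common
  keep_p <- pred$date %in% common
  if (verbose) {
    message(sprintf("date intersection: %d days (trimmed %d from observed, %d from predicted)",
                    length(common), sum(!keep_o), sum(!keep_p)))
  }
  merged <- new_raw_series(common,
                           ifelse(is.na(obs$value[keep_o]) | is.na(pred$value[keep_p]),
                                  NA_real_, obs$value[keep_o]))
  run <- longest_complete_run(merged, min_days, days_per_year)
  dates <- series_dates(run)
  o <- daily_series(obs$value[match(dates, obs$date)], dates[1], days_per_year)
  p <- daily_series(pred$value[match(dates, pred$date)], dates[1], days_per_year)
  met <- band_metrics(o, p, spec)
  if (!is.null(output)) {
    utils::write.csv(met, output, row.names = FALSE)
  }
  invisible(met)
}

#' Generate small deterministic fixture CSV pairs
#'
#' Writes observed/predicted daily-series CSV pairs (n = 365, one year)
#' covering three cases: no error (`noerror`), seasonal error at band 1
#' (`band1_sigma08`), and acute error at band 6 (`band6_sigma08`), each
#' with sigma_c = 0.8. Runs with the same seed produce byte-identical
#' files.
#'
#' @param seed Integer seed.
#' @param outdir Output directory (created if absent).
#' @return Invisibly, a character vector of the files written.
#' @export
generate_fixtures <- function(seed = 1, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg <- exposure_sim_config(n = 365)
  cases <- list(noerror = NULL, band1_sigma08 = 1L, band6_sigma08 = 6L)
  files <- character(0)
  for (nm in names(cases)) {
    obs <- simulate_observed(cfg, seed = derive_seed(seed, match(nm, names(cases)), 1))
    if (is.null(cases[[nm]])) {
      pair <- make_prediction(obs, error_config(0, 1),
                              error_series = series_like(rep(0, cfg$n), obs$observed))
    } else {
      pair <- make_prediction(obs, error_config(0.8, cases[[nm]]),
                              seed = derive_seed(seed, match(nm, names(cases)), 2))
    }
    fo <- file.path(outdir, paste0(nm, "_observed.csv"))
    fp <- file.path(outdir, paste0(nm, "_predicted.csv"))
    write_series(pair$observed, fo)
    write_series(pair$predicted, fp)
    files <- c(files, fo, fp)
  }
  invisible(files)
}
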