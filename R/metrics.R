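#' Overall model performance metrics
#'
#' Compares a predicted series to a reference (observed) series with three
#' whole-series measures: Pearson correlation r, RMSE scaled by the sample
#' standard deviation of the reference, and the log variance ratio
#' LVR = log(Var(pred) / Var(obs)). RMSE uses the 1/n average of squared
#' differences; all sample variances and SDs use the n - 1 denominator.
#' A correlation that is undefined because the predictions are constant is
#' reported as `NA` (R's typed missing marker); a constant reference series
#' is an error, since the scaled RMSE and LVR are then undefined.
#'
#' @param obs Reference `daily_series` (ground-truth observations).
#' @param pred Predicted `daily_series` of the same length.
#' @param band_label Label for the output row; default `"overall"`.
#' @return A one-row data frame with columns `band`, `r`, `rmse_scaled`,
#'   `lvr`.
#' @examples
#' z <- daily_series(rnorm(365, 10, 3))
#' overall_metrics(z, z) # identity: r = 1, rmse_scaled = 0, lvr = 0
#' @export
overall_metrics <- function(obs, pred, band_label = "overall") {
  stopifnot(is_daily_series(obs), is_daily_series(pred))
  check_same_length(obs, pred)
  if (length(obs) < 3L) stop("metrics need at least 3 days")
  metric_row(series_values(obs), series_values(pred), band_label,
             constant_obs_is_error = TRUE)
}

metric_row <- function(o, p, band_label, constant_obs_is_error = FALSE,
                       min_var = 0) {
  v_o <- stats::var(o)
  v_p <- stats::var(p)
  if (v_o <= min_var) {
    if (constant_obs_is_error) {
      stop("reference series has zero variance; scaled RMSE and LVR are undefined")
    }
    return(data.frame(band = band_label, r = NA_real_,
                      rmse_scaled = NA_real_, lvr = NA_real_,
                      stringsAsFactors = FALSE))
  }
  r <- if (v_p <= 0) NA_real_ else stats::cor(o, p)
  rmse <- sqrt(mean((p - o)^2))
  data.frame(band = band_label,
             r = r,
             rmse_scaled = rmse / sqrt(v_o),
             lvr = log(v_p / v_o),
             stringsAsFactors = FALSE)
}

#' Frequency band model performance metrics
#'
#' Decomposes both series into frequency bands and computes, for each band k,
#' the same three measures as [overall_metrics()] from the band-k components:
#' r_(k) = Cor(pred_k, obs_k), RMSE_(k) = sqrt(mean((pred_k - obs_k)^2))
#' scaled by the SD of obs_k, and LVR_(k) = log(Var(pred_k) / Var(obs_k)).
#' A band in which the reference component is numerically constant yields
#' `NA` metrics for that band rather than an error, since real series often
#' carry no energy in some bands.
#'
#' @param obs Reference `daily_series`.
#' @param pred Predicted `daily_series` of the same length.
#' @param spec A [band_spec()].
#' @param include_overall Prepend the overall metrics row? Default `TRUE`.
#' @return A data frame with one row per band (and optionally an "overall"
#'   row), columns `band`, `r`, `rmse_scaled`, `lvr`.
#' @examples
#' z <- daily_series(rnorm(365, 10, 3))
#' band_metrics(z, z)[, c("band", "r", "rmse_scaled")]
#' @export
band_metrics <- function(obs, pred, spec = default_band_spec(),
                         include_overall = TRUE) {
  stopifnot(is_daily_series(obs), is_daily_series(pred))
  check_same_length(obs, pred)
  dob <- decompose_series(obs, spec)
  dpr <- decompose_series(pred, spec)
  # a band whose reference variance is below 1e-20 of the total carries only
  # floating-point leakage; its metrics are undefined, not noise
  min_var <- 1e-20 * stats::var(series_values(obs))
  rows <- lapply(seq_len(n_bands(spec)), function(k) {
    metric_row(series_values(dob$components[[k]]),
               series_values(dpr$components[[k]]),
               band_label = as.character(k), min_var = min_var)
  })
  out <- do.call(rbind, rows)
  if (include_overall) out <- rbind(overall_metrics(obs, pred), out)
  rownames(out) <- NULL
  out
}
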