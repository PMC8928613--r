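#' Split an exposure series into smooth and acute components
#'
#' Regresses the exposure series on a natural cubic spline of the day index
#' with `split_df` degrees of freedom (default 24 over the whole series,
#' about 8 per year on a 3-year record - enough to capture seasonal and
#' monthly trends). The fitted values carry the smooth trend; the residuals
#' carry the sub-monthly, acute variation that drives short-term health
#' associations. Interior knots sit at equally spaced quantiles of the day
#' index, boundary knots at its range; an intercept is always included.
#'
#' @param z Exposure `daily_series` (concentration in ug/m3).
#' @param split_df Non-intercept spline degrees of freedom (default 24).
#' @return A list of class `exposure_split` with `fitted` and `residual`
#'   `daily_series` (summing elementwise to `z`) and `split_df`.
#' @export
split_exposure <- function(z, split_df = 24) {
  stopifnot(is_daily_series(z))
  n <- length(z)
  split_df <- as.integer(split_df)
  if (split_df < 2L) stop("'split_df' must be at least 2")
  if (n <= split_df + 1L) stop("series too short for the requested spline df")
  basis <- splines::ns(seq_len(n), df = split_df)
  X <- cbind(1, basis)
  fit <- stats::lm.fit(X, series_values(z))
  if (fit$rank < ncol(X)) stop("spline basis is rank-deficient")
  structure(list(fitted = series_like(fit$fitted.values, z),
                 residual = series_like(fit$residuals, z),
                 split_df = split_df),
            class = "exposure_split")
}

#' Configuration for the daily health-count simulation
#'
#' Daily counts (deaths or emergency-department visits) are Poisson with
#' mean mu(t) = exp(beta0 + beta1 * z_residual(t) + fitted_coef * z_fitted(t)),
#' where the residual/fitted split comes from [split_exposure()]. The
#' defaults give a baseline log-rate beta0 = 5 (about 200 counts per day,
#' reflecting cardiorespiratory ED visits in large US cities) and an acute
#' association beta1 = log(1.1)/10, i.e. relative risk 1.1 per 10 ug/m3
#' PM2.5.
#'
#' @param beta0 Baseline log-rate (default 5).
#' @param beta1 Acute log-relative-rate per ug/m3 (default log(1.1)/10).
#' @param fitted_coef Coefficient on the smooth exposure component
#'   (default 0.03).
#' @param split_df Spline df for the exposure split (default 24).
#' @return An object of class `health_sim_config`.
#' @export
health_sim_config <- function(beta0 = 5, beta1 = log(1.1) / 10,
                              fitted_coef = 0.03, split_df = 24) {
  if (split_df < 2) stop("'split_df' must be at least 2")
  structure(list(beta0 = beta0, beta1 = beta1, fitted_coef = fitted_coef,
                 split_df = as.integer(split_df)),
            class = "health_sim_config")
}

#' Simulate daily health counts from a split exposure series
#'
#' @param split An `exposure_split` from [split_exposure()].
#' @param cfg A [health_sim_config()].
#' @param seed Optional integer seed.
#' @return A `daily_series` of nonnegative integer counts.
#' @export
simulate_counts <- function(split, cfg = health_sim_config(), seed = NULL) {
  stopifnot(inherits(split, "exposure_split"), inherits(cfg, "health_sim_config"))
  if (!is.null(seed)) set.seed(seed)
  eta <- cfg$beta0 + cfg$beta1 * series_values(split$residual) +
    cfg$fitted_coef * series_values(split$fitted)
  if (any(eta > 700)) stop("Poisson mean overflows: log-mean exceeds 700")
  mu <- exp(eta)
  series_like(stats::rpois(length(mu), mu), split$residual)
}
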