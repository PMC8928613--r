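#' Summarize one simulation condition across replicates
#'
#' A condition is one (sigma_c, error band) cell of the simulation grid.
#' Given the per-replicate health fits and model-performance metric tables,
#' computes the percent relative mean bias of the estimated acute
#' association, 100 * mean(beta1_hat - beta1) / beta1, the health
#' association RMSE, sqrt(mean((beta1_hat - beta1)^2)), and the arithmetic
#' mean of each performance metric per band. Non-converged fits are dropped
#' with a warning.
#'
#' @param fits List of `health_fit` objects (one per replicate), or `NULL`
#'   when only exposure metrics are summarized.
#' @param beta1_true True acute log-relative-rate used in the simulation.
#' @param metrics List of metric data frames from [band_metrics()], one per
#'   replicate.
#' @param condition Optional list/vector identifying the condition
#'   (e.g. `list(sigma_c = 0.8, error_band = 6)`).
#' @return An object of class `condition_summary`: a list with
#'   `mean_metrics` (data frame of per-band metric means),
#'   `pct_rel_mean_bias`, `health_rmse`, `n_replicates`, `n_converged`,
#'   `condition`.
#' @export
summarize_condition <- function(fits = NULL, beta1_true = log(1.1) / 10,
                                metrics, condition = NULL) {
  if (length(metrics) < 2L) stop("need at least 2 replicates to summarize")
  stacked <- do.call(rbind, metrics)
  mean_metrics <- stats::aggregate(
    stacked[c("r", "rmse_scaled", "lvr")],
    by = list(band = stacked$band), FUN = mean)
  # keep the band ordering of the first replicate (overall first)
  mean_metrics <- mean_metrics[match(metrics[[1]]$band, mean_metrics$band), ]
  rownames(mean_metrics) <- NULL

  pct_bias <- NA_real_
  rmse <- NA_real_
  n_conv <- NA_integer_
  if (!is.null(fits)) {
    conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
    if (!all(conv)) {
      warning(sprintf("dropping %d non-converged fit(s) of %d",
                      sum(!conv), length(fits)))
    }
    if (sum(conv) < 2L) stop("fewer than 2 converged fits in this condition")
    b <- vapply(fits[conv], function(f) f$beta1_hat, numeric(1))
    pct_bias <- 100 * mean(b - beta1_true) / beta1_true
    rmse <- sqrt(mean((b - beta1_true)^2))
    n_conv <- sum(conv)
  }
  structure(list(condition = condition,
                 mean_metrics = mean_metrics,
                 pct_rel_mean_bias = pct_bias,
                 health_rmse = rmse,
                 n_replicates = length(metrics),
                 n_converged = n_conv),
            class = "condition_summary")
}

#' Flatten condition summaries to one row per condition
#'
#' @param summaries List of `condition_summary` objects.
#' @param bands Which metric scopes to spread into columns
#'   (default `c("overall", "6")`).
#' @return A data frame with the condition identifiers, the health
#'   measures, and `<metric>_<scope>` columns (scope `overall` or
#'   `band<k>`).
#' @export
condition_table <- function(summaries, bands = c("overall", "6")) {
  rows <- lapply(summaries, function(s) {
    row <- as.data.frame(s$condition, stringsAsFactors = FALSE)
    row$pct_rel_mean_bias <- s$pct_rel_mean_bias
    row$health_rmse <- s$health_rmse
    row$n_replicates <- s$n_replicates
    row$n_converged <- s$n_converged
    for (b in bands) {
      m <- s$mean_metrics[s$mean_metrics$band == b, ]
      scope <- if (b == "overall") "overall" else paste0("band", b)
      row[[paste0("r_", scope)]] <- m$r
      row[[paste0("rmse_scaled_", scope)]] <- m$rmse_scaled
      row[[paste0("lvr_", scope)]] <- m$lvr
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' R-squared of health measures against condition-mean performance metrics
#'
#' For each pair of a health measure (percent relative mean bias, health
#' association RMSE) and a performance metric (correlation r, scaled RMSE,
#' LVR) at each scope (acute band 6 and overall by default), fits an
#' ordinary least-squares straight line of the health measure on the
#' condition-mean metric across the simulation conditions and reports the
#' R-squared (the squared Pearson correlation). A metric that is constant
#' across conditions yields `NA`.
#'
#' @param summaries List of `condition_summary` objects (>= 3), or a data
#'   frame already produced by [condition_table()].
#' @param bands Metric scopes (default `c("6", "overall")`).
#' @return A data frame with columns `health_measure`, `metric`, `scope`,
#'   `r_squared`.
#' @export
association_r2 <- function(summaries, bands = c("6", "overall")) {
  tab <- if (is.data.frame(summaries)) summaries else condition_table(summaries, bands)
  if (nrow(tab) < 3L) stop("need at least 3 conditions for a straight-line fit")
  out <- expand.grid(health_measure = c("rel_mean_bias", "health_rmse"),
                     metric = c("r", "rmse_scaled", "lvr"),
                     scope = ifelse(bands == "overall", "overall",
                                    paste0("band", bands)),
                     stringsAsFactors = FALSE)
  hm_col <- c(rel_mean_bias = "pct_rel_mean_bias", health_rmse = "health_rmse")
  out$r_squared <- vapply(seq_len(nrow(out)), function(i) {
    y <- tab[[hm_col[[out$health_measure[i]]]]]
    x <- tab[[paste0(out$metric[i], "_", out$scope[i])]]
    if (is.null(x) || stats::var(x) < 1e-14 || stats::var(y) < 1e-14) return(NA_real_)
    stats::cor(x, y)^2
  }, numeric(1))
  out
}

#' Run the band-error simulation study
#'
#' The full pipeline: simulate observed PM2.5-like series; for each, build
#' predictions carrying classical error at each band of `error_bands`
#' scaled by each magnitude in `sigma_c_grid` (one standardized error draw
#' per replicate and band, reused across magnitudes); compute overall and
#' per-band performance metrics on the concentration scale; simulate daily
#' health counts from the observed series; fit the acute health-association
#' regression to the counts and each predicted exposure; and summarize each
#' condition across replicates. The heavy spline basis for the health model
#' is built once and shared by every fit.
#'
#' @param n_replicates Number of simulated observed series (default 25, the
#'   desk-scale study; the full-scale study uses 100).
#' @param seed Master integer seed; replicate- and purpose-specific child
#'   seeds are derived deterministically from it.
#' @param sigma_c_grid Error magnitudes (default `c(0.2, 0.4, 0.6, 0.8)`).
#' @param error_bands Bands receiving error (default `1:6`).
#' @param cfg An [exposure_sim_config()].
#' @param health_cfg A [health_sim_config()], or `NULL` to skip the health
#'   side (metrics only, much faster).
#' @param df_per_year Health-model spline df per year (default 280).
#' @return An object of class `freqband_study`: a list with `conditions`
#'   (the [condition_table()] data frame), `r2` (the [association_r2()]
#'   table, `NULL` when health fitting is skipped), `summaries` (the
#'   `condition_summary` list) and the settings used.
#' @export
run_study <- function(n_replicates = 25, seed = 1,
                      sigma_c_grid = c(0.2, 0.4, 0.6, 0.8),
                      error_bands = 1:6,
                      cfg = exposure_sim_config(),
                      health_cfg = health_sim_config(),
                      df_per_year = 280) {
  if (n_replicates < 2L) stop("need at least 2 replicates")
  fit_health <- !is.null(health_cfg)
  basis <- if (fit_health) {
    health_spline_basis(cfg$n, df_per_year, cfg$days_per_year)
  }
  grid <- expand.grid(sigma_c = sigma_c_grid, error_band = error_bands)
  n_cond <- nrow(grid)
  metrics <- replicate(n_cond, vector("list", n_replicates), simplify = FALSE)
  fits <- if (fit_health) {
    replicate(n_cond, vector("list", n_replicates), simplify = FALSE)
  }
  for (i in seq_len(n_replicates)) {
    obs <- simulate_observed(cfg, seed = derive_seed(seed, i, 1))
    counts <- NULL
    if (fit_health) {
      split <- split_exposure(obs$observed, health_cfg$split_df)
      counts <- simulate_counts(split, health_cfg,
                                seed = derive_seed(seed, i, 2))
    }
    for (b in error_bands) {
      w <- simulate_band_error(cfg$n, b, cfg$spec, cfg$days_per_year,
                               seed = derive_seed(seed, i, 10, b))
      for (ci in which(grid$error_band == b)) {
        pair <- make_prediction(obs, error_config(grid$sigma_c[ci], b),
                                error_series = w)
        metrics[[ci]][[i]] <- band_metrics(pair$observed, pair$predicted,
                                           cfg$spec)
        if (fit_health) {
          fits[[ci]][[i]] <- fit_health_association(counts, pair$predicted,
                                                    basis = basis)
        }
      }
    }
  }
  beta1_true <- if (fit_health) health_cfg$beta1 else log(1.1) / 10
  summaries <- lapply(seq_len(n_cond), function(ci) {
    summarize_condition(fits = if (fit_health) fits[[ci]],
                        beta1_true = beta1_true,
                        metrics = metrics[[ci]],
                        condition = list(sigma_c = grid$sigma_c[ci],
                                         error_band = grid$error_band[ci]))
  })
  conditions <- condition_table(summaries)
  r2 <- if (fit_health && n_cond >= 3L) association_r2(summaries)
  structure(list(conditions = conditions, r2 = r2, summaries = summaries,
                 settings = list(n_replicates = n_replicates, seed = seed,
                                 sigma_c_grid = sigma_c_grid,
                                 error_bands = error_bands,
                                 cfg = cfg, health_cfg = health_cfg,
                                 df_per_year = df_per_year)),
            class = "freqband_study")
}

#' @export
print.freqband_study <- function(x, ...) {
  s <- x$settings
  cat(sprintf("<freqband_study> %d replicates x %d conditions (seed %d)\n",
              s$n_replicates, nrow(x$conditions), s$seed))
  print(utils::head(x$conditions, 8))
  if (!is.null(x$r2)) {
    cat("\nR-squared of health measures vs condition-mean metrics:\n")
    print(x$r2)
  }
  invisible(x)
}
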