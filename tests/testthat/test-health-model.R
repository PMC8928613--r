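test_that("the IRLS fit matches the quasi-Poisson GLM oracle", {
  # small crafted dataset with a low-df adjustment basis so glm is cheap
  set.seed(31)
  n <- 120
  expo <- daily_series(exp(rnorm(n, 2, 0.4)))
  basis <- health_spline_basis(n, df_per_year = 12) # 2 total df
  eta <- 3 + 0.05 * as.numeric(expo)
  counts <- daily_series(rpois(n, exp(eta)))
  fit <- fit_health_association(counts, expo, basis = basis)
  g <- stats::glm(as.numeric(counts) ~ as.numeric(expo) + basis$q - 1,
                  family = stats::quasipoisson())
  expect_equal(fit$beta1_hat, unname(coef(g)[1]), tolerance = 1e-8)
  # the two fitters stop at slightly different IRLS iterates, so SE and
  # dispersion agree to the convergence tolerance, not machine precision
  expect_equal(fit$se, unname(summary(g)$coefficients[1, 2]), tolerance = 1e-5)
  expect_equal(fit$dispersion, summary(g)$dispersion, tolerance = 1e-5)
  expect_true(fit$converged)
})

test_that("the oracle agreement holds at a moderate spline dimension", {
  set.seed(32)
  obs <- simulate_observed(exposure_sim_config(n = 730), seed = 33)
  split <- split_exposure(obs$observed)
  counts <- simulate_counts(split, seed = 34)
  basis <- health_spline_basis(730, df_per_year = 30) # 60 total df
  fit <- fit_health_association(counts, obs$observed, basis = basis)
  g <- stats::glm(as.numeric(counts) ~ as.numeric(obs$observed) + basis$q - 1,
                  family = stats::quasipoisson())
  expect_equal(fit$beta1_hat, unname(coef(g)[1]), tolerance = 1e-8)
  expect_equal(fit$se, unname(summary(g)$coefficients[1, 2]), tolerance = 1e-5)
})

test_that("dispersion is near one on correctly specified Poisson data", {
  disp <- sapply(1:5, function(i) {
    obs <- simulate_observed(seed = 800 + i)
    split <- split_exposure(obs$observed)
    counts <- simulate_counts(split, seed = 900 + i)
    fit_health_association(counts, obs$observed,
                           basis = health_spline_basis(1095))$dispersion
  })
  expect_equal(mean(disp), 1, tolerance = 0.1)
})

test_that("acute-band classical error attenuates the association toward zero", {
  basis <- health_spline_basis(1095)
  bias <- sapply(c(0, 0.4, 0.8), function(sc) {
    b <- sapply(1:8, function(i) {
      obs <- simulate_observed(seed = 1000 + i)
      split <- split_exposure(obs$observed)
      counts <- simulate_counts(split, seed = 1100 + i)
      pair <- make_prediction(obs, error_config(sc, 6), seed = 1200 + i)
      fit_health_association(counts, pair$predicted, basis = basis)$beta1_hat
    })
    mean(b) - log(1.1) / 10
  })
  expect_lt(bias[2], 0)          # attenuation is negative bias
  expect_lt(bias[3], bias[2])    # and grows with the error magnitude
})

test_that("degenerate exposure and mismatched basis are errors", {
  counts <- daily_series(rpois(100, 100))
  expect_error(fit_health_association(counts, daily_series(rep(5, 100)),
                                      basis = health_spline_basis(100, 12)),
               "constant")
  expect_error(fit_health_association(counts, rand_series(100, 35),
                                      basis = health_spline_basis(200, 12)),
               "does not match")
  expect_error(health_spline_basis(100, df_per_year = 400), "must be <")
})

test_that("condition summaries aggregate bias and RMSE as stated", {
  bt <- log(1.1) / 10
  met <- band_metrics(rand_series(365, 36), rand_series(365, 37))
  # all estimates exactly true: zero bias, zero RMSE
  s <- summarize_condition(list(fake_fit(bt), fake_fit(bt)), bt,
                           metrics = list(met, met))
  expect_equal(s$pct_rel_mean_bias, 0)
  expect_equal(s$health_rmse, 0)
  # symmetric +-10% errors: zero bias, RMSE = 0.1 * beta1
  s2 <- summarize_condition(list(fake_fit(0.9 * bt), fake_fit(1.1 * bt)), bt,
                            metrics = list(met, met))
  expect_equal(s2$pct_rel_mean_bias, 0, tolerance = 1e-10)
  expect_equal(s2$health_rmse, 0.1 * bt, tolerance = 1e-10)
  # non-converged fits are dropped with a warning
  expect_warning(
    s3 <- summarize_condition(list(fake_fit(bt), fake_fit(bt),
                                   fake_fit(99, converged = FALSE)), bt,
                              metrics = list(met, met, met)),
    "non-converged")
  expect_equal(s3$n_converged, 2L)
  # mean metrics preserve the per-band structure
  expect_equal(s$mean_metrics$band, met$band)
  expect_equal(s$mean_metrics$r, met$r)
})

test_that("association R-squared is 1 for exact lines and near 0 under permutation", {
  set.seed(38)
  tab <- data.frame(sigma_c = rep(c(0.2, 0.4, 0.6, 0.8), 6),
                    error_band = rep(1:6, each = 4))
  tab$rmse_scaled_band6 <- runif(24, 0.1, 2)
  tab$r_band6 <- runif(24, 0.3, 1)
  tab$lvr_band6 <- runif(24, 0, 1)
  tab$rmse_scaled_overall <- runif(24, 0.1, 2)
  tab$r_overall <- runif(24, 0.3, 1)
  tab$lvr_overall <- runif(24, 0, 1)
  tab$pct_rel_mean_bias <- -30 * tab$rmse_scaled_band6 + 2 # exact line
  tab$health_rmse <- abs(tab$pct_rel_mean_bias) / 1e4
  r2 <- association_r2(tab)
  exact <- r2$r_squared[r2$health_measure == "rel_mean_bias" &
                        r2$metric == "rmse_scaled" & r2$scope == "band6"]
  expect_equal(exact, 1, tolerance = 1e-12)
  expect_true(all(r2$r_squared >= 0 & r2$r_squared <= 1, na.rm = TRUE))
  # permuting the health measure destroys the association
  tab$pct_rel_mean_bias <- sample(tab$pct_rel_mean_bias)
  r2p <- association_r2(tab)
  perm <- r2p$r_squared[r2p$health_measure == "rel_mean_bias" &
                        r2p$metric == "rmse_scaled" & r2p$scope == "band6"]
  expect_lt(perm, 0.4)
  # constant metric yields the undefined marker
  tab$r_band6 <- 0.5
  r2c <- association_r2(tab)
  expect_true(is.na(r2c$r_squared[r2c$metric == "r" & r2c$scope == "band6"][1]))
})
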