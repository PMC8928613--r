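test_that("the base signal is standardized and band-limited to its active bands", {
  cfg <- exposure_sim_config()
  x <- simulate_base_signal(cfg, seed = 11)
  expect_equal(var(as.numeric(x)), 1, tolerance = 1e-6)
  expect_equal(mean(as.numeric(x)), 0, tolerance = 1e-8)
  d <- decompose_series(x)
  vars <- sapply(d$components, function(c) var(as.numeric(c)))
  expect_gt(sum(vars[c(1, 2, 6)]) / sum(vars), 0.999)
})

test_that("raising the seasonal variance shifts the variance share to band 1", {
  cfg <- exposure_sim_config(band_variances = c("1" = 4, "2" = 1, "6" = 1))
  x <- simulate_base_signal(cfg, seed = 12)
  expect_equal(var(as.numeric(x)), 1, tolerance = 1e-6)
  d <- decompose_series(x)
  vars <- sapply(d$components, function(c) var(as.numeric(c)))
  expect_equal(vars[1] / sum(vars), 4 / 6, tolerance = 0.02)
})

test_that("a band holding no integer frequency is rejected", {
  spec <- band_spec(rbind(c(0.1, 0.9), c(0.9, 183)))
  cfg <- exposure_sim_config(band_variances = c("1" = 1), spec = spec)
  expect_error(simulate_base_signal(cfg, seed = 1), "no integer")
})

test_that("observed concentrations follow the log-normal construction", {
  cfg <- exposure_sim_config()
  sim <- simulate_observed(cfg, seed = 13)
  z <- as.numeric(sim$observed)
  x <- as.numeric(sim$log_observed)
  expect_true(all(z > 0))
  # exact closed-form link between the log signal and the concentrations
  expect_equal(z, exp(x * 0.6 + 1.9), tolerance = 1e-12)
  # across replicates the log series has the configured mean and SD and the
  # concentration median sits at exp(mu_x)
  logz <- unlist(lapply(1:20, function(i) {
    log(as.numeric(simulate_observed(cfg, seed = 100 + i)$observed))
  }))
  expect_equal(mean(logz), 1.9, tolerance = 0.01)
  expect_equal(sd(logz), 0.6, tolerance = 0.01)
  expect_equal(median(exp(logz)), exp(1.9), tolerance = 0.2)
})

test_that("band error is unit-variance, band-confined, and independent of the signal", {
  w <- simulate_band_error(1095, 6, seed = 14)
  expect_equal(var(as.numeric(w)), 1, tolerance = 1e-10)
  d <- decompose_series(w)
  energy <- sapply(d$components, function(c) sum(as.numeric(c)^2))
  expect_lt(sum(energy[-6]) / sum(energy), 1e-10)
  # noise and signal draws are independent: correlations centered at zero
  cors <- sapply(1:30, function(i) {
    x <- simulate_base_signal(exposure_sim_config(), seed = 200 + i)
    wk <- simulate_band_error(1095, 6, seed = 500 + i)
    cor(as.numeric(x), as.numeric(wk))
  })
  expect_lt(abs(mean(cors)), 3 / sqrt(30 * 1095 / 3))
})

test_that("a zero-magnitude error reproduces the observations exactly", {
  sim <- simulate_observed(seed = 15)
  pair <- make_prediction(sim, error_config(0, 3), seed = 16)
  expect_identical(as.numeric(pair$predicted), as.numeric(pair$observed))
})

test_that("identical seeds give bitwise-identical simulations", {
  a <- simulate_observed(seed = 17)
  b <- simulate_observed(seed = 17)
  expect_identical(as.numeric(a$observed), as.numeric(b$observed))
  wa <- simulate_band_error(365, 2, seed = 18)
  wb <- simulate_band_error(365, 2, seed = 18)
  expect_identical(as.numeric(wa), as.numeric(wb))
})

test_that("error confinement is exact on the log scale", {
  sim <- simulate_observed(seed = 19)
  pair <- make_prediction(sim, error_config(0.8, 2), seed = 20)
  x <- sim$log_observed
  x_star <- daily_series(as.numeric(x) + 0.8 * as.numeric(pair$log_error_component))
  m <- band_metrics(x, x_star, include_overall = FALSE)
  # bands carrying signal but no error: identity metrics
  for (k in c(1, 6)) {
    expect_equal(m$r[k], 1, tolerance = 1e-6)
    expect_equal(m$rmse_scaled[k], 0, tolerance = 1e-6)
    expect_equal(m$lvr[k], 0, tolerance = 1e-6)
  }
  # bands with no signal energy at all: undefined, not noise
  expect_true(all(is.na(m$r[3:5])))
  expect_lt(m$r[2], 1 - 1e-3)
})

test_that("degradation at the error band is monotone in the error magnitude", {
  sigmas <- c(0.2, 0.4, 0.6, 0.8)
  rmse <- matrix(NA_real_, 50, length(sigmas))
  rr <- matrix(NA_real_, 50, length(sigmas))
  for (i in 1:50) {
    sim <- simulate_observed(exposure_sim_config(n = 365), seed = 300 + i)
    w <- simulate_band_error(365, 6, seed = 700 + i)
    for (s in seq_along(sigmas)) {
      pair <- make_prediction(sim, error_config(sigmas[s], 6), error_series = w)
      m <- band_metrics(pair$observed, pair$predicted, include_overall = FALSE)
      rmse[i, s] <- m$rmse_scaled[6]
      rr[i, s] <- m$r[6]
    }
  }
  expect_true(all(diff(colMeans(rmse)) > 0))
  expect_true(all(diff(colMeans(rr)) < 0))
})
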