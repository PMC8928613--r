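test_that("identity and pure variance-scaling give the closed-form metrics", {
  z <- rand_series(365, 1)
  m <- overall_metrics(z, z)
  expect_equal(m$r, 1)
  expect_equal(m$rmse_scaled, 0)
  expect_equal(m$lvr, 0)
  # doubling deviations about the mean scales the variance by 4
  scaled <- daily_series(mean(z) + 2 * (as.numeric(z) - mean(z)))
  m2 <- overall_metrics(z, scaled)
  expect_equal(m2$r, 1)
  expect_equal(m2$lvr, log(4), tolerance = 1e-12)
})

test_that("metrics match the hand-computed four-point example", {
  # obs (1,2,3,4), pred (1,2,3,8): explicit sums give
  # cov = 11/3, var_obs = 5/3, var_pred = 29/3,
  # r = 11/sqrt(145), rmse = 2, rmse/sd_obs = 2/sqrt(5/3), lvr = log(29/5)
  obs <- daily_series(c(1, 2, 3, 4))
  pred <- daily_series(c(1, 2, 3, 8))
  m <- overall_metrics(obs, pred)
  expect_equal(m$r, 11 / sqrt(145), tolerance = 1e-12)
  expect_equal(m$rmse_scaled, 2 / sqrt(5 / 3), tolerance = 1e-12)
  expect_equal(m$lvr, log(29 / 5), tolerance = 1e-12)
})

test_that("degenerate variance is an error for the reference, NA for the prediction", {
  const <- daily_series(rep(3, 10))
  z <- rand_series(10, 2)
  expect_error(overall_metrics(const, z), "zero variance")
  m <- overall_metrics(z, const)
  expect_true(is.na(m$r))
  expect_equal(m$lvr, -Inf)
})

test_that("the log variance ratio is antisymmetric under role swap", {
  a <- rand_series(365, 3)
  b <- rand_series(365, 4)
  expect_equal(overall_metrics(a, b)$lvr, -overall_metrics(b, a)$lvr,
               tolerance = 1e-12)
})

test_that("band metrics are identity for a perfect prediction in every band", {
  z <- rand_series(1095, 5)
  m <- band_metrics(z, z)
  expect_equal(nrow(m), 7) # overall + 6 bands
  expect_equal(m$r, rep(1, 7), tolerance = 1e-12)
  expect_equal(m$rmse_scaled, rep(0, 7))
  expect_equal(m$lvr, rep(0, 7))
})

test_that("band-limited additive noise degrades only its own band", {
  z <- rand_series(1095, 6)
  w6 <- simulate_band_error(1095, 6, seed = 7)
  noisy <- daily_series(as.numeric(z) + 0.5 * as.numeric(w6))
  m <- band_metrics(z, noisy, include_overall = FALSE)
  for (k in 1:5) {
    expect_equal(m$r[k], 1, tolerance = 1e-6)
    expect_equal(m$rmse_scaled[k], 0, tolerance = 1e-6)
    expect_equal(m$lvr[k], 0, tolerance = 1e-6)
  }
  expect_lt(m$r[6], 1 - 1e-3)
  expect_gt(m$rmse_scaled[6], 0.1)
})

test_that("a band with no reference energy yields NA metrics, not a failure", {
  t <- 1:1095
  z <- daily_series(cos(2 * pi * 3 * t / 365)) # band-1 signal only
  noisy <- daily_series(as.numeric(z) + 0.1 * as.numeric(simulate_band_error(1095, 4, seed = 8)))
  m <- band_metrics(z, noisy, include_overall = FALSE)
  expect_true(is.na(m$r[4]))   # reference component is (numerically) zero
  expect_false(anyNA(m$r[1]))
})

test_that("metric bounds hold across random pairs", {
  for (seed in 1:10) {
    a <- rand_series(400, seed)
    b <- rand_series(400, seed + 100)
    m <- band_metrics(a, b)
    defined <- !is.na(m$r)
    expect_true(all(m$r[defined] >= -1 & m$r[defined] <= 1))
    expect_true(all(m$rmse_scaled[defined] >= 0))
  }
})
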