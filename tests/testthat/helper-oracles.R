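# Independent oracles, deliberately built without the package's own
# decomposition or index-mapping code paths.

# Brute-force O(n^2) DFT band components: explicit cosine/sine sums per
# Fourier index, with an index-to-band rule derived directly from the
# half-open band intervals (mirror index min(j, n - j) carries the
# frequency; sub-band frequencies, including the mean, go to band 1).
brute_dft_components <- function(x, days_per_year = 365,
                                 bands = rbind(c(1, 6), c(6, 12), c(12, 26),
                                               c(26, 52), c(52, 104), c(104, 183))) {
  n <- length(x)
  K <- nrow(bands)
  tt <- 0:(n - 1)
  band_of <- function(j) {
    f <- min(j, n - j) * days_per_year / n
    if (f < bands[1, 1]) return(1L)
    for (k in seq_len(K)) {
      if (f >= bands[k, 1] && f < bands[k, 2]) return(k)
    }
    stop("frequency not covered: ", f)
  }
  comps <- matrix(0, n, K)
  for (j in 0:(n - 1)) {
    cosj <- cos(2 * pi * j * tt / n)
    sinj <- sin(2 * pi * j * tt / n)
    re <- sum(x * cosj)
    im <- -sum(x * sinj)
    k <- band_of(j)
    comps[, k] <- comps[, k] + (re * cosj - im * sinj) / n
  }
  comps
}

# convenience: a reproducible random daily series
rand_series <- function(n, seed, mean = 10, sd = 3, days_per_year = 365) {
  set.seed(seed)
  daily_series(rnorm(n, mean, sd), days_per_year = days_per_year)
}

# fake converged health_fit for aggregation tests
fake_fit <- function(beta1, converged = TRUE) {
  structure(list(beta1_hat = beta1, se = 1e-3, dispersion = 1,
                 converged = converged, n_used = 1095L,
                 iterations = 4L, spline_df = 840L),
            class = "health_fit")
}
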