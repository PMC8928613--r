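#' Map Fourier indices to frequency bands
#'
#' For a series of length n, Fourier index j in 0..floor(n/2) corresponds to
#' frequency f_j = j * days_per_year / n cycles per year. Each index is
#' assigned to the band whose half-open interval \[low, high) contains f_j;
#' ties at a boundary therefore go to the upper band. Indices below the first
#' band's lower bound - including j = 0, which carries the series mean - are
#' assigned to band 1 when the spec's
#' `include_sub_band_frequencies_in_first` flag is set (the default), so the
#' partition of \[0, n/2) is complete and the band components can sum back to
#' the input.
#'
#' @param n Series length in days (>= 2).
#' @param days_per_year Days per year (converts index to cycles/year).
#' @param spec A [band_spec()].
#' @return Integer vector of band indices, one per Fourier index
#'   j = 0, ..., floor(n/2), with the frequencies in cycles/year as an
#'   attribute `"freq"`.
#' @examples
#' m <- assign_frequencies(1095, 365, default_band_spec())
#' m[4] # index j = 3 -> 1 cycle/yr -> band 1
#' @export
assign_frequencies <- function(n, days_per_year = 365, spec = default_band_spec()) {
  stopifnot(inherits(spec, "band_spec"))
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("'n' must be an integer >= 2")
  j <- 0:(n %/% 2L)
  f <- j * days_per_year / n
  K <- n_bands(spec)
  band <- rep(NA_integer_, length(j))
  for (k in seq_len(K)) {
    band[f >= spec$bands[k, 1] & f < spec$bands[k, 2]] <- k
  }
  below <- f < spec$bands[1, 1]
  if (any(below)) {
    if (spec$include_sub_band_frequencies_in_first) {
      band[below] <- 1L
    } else {
      stop(sprintf(paste0("frequencies below the first band are present ",
                          "(lowest: %.6g cycles/yr at index j = %d) and the spec ",
                          "excludes them from band 1"),
                   min(f[below]), j[which(below)[1]]))
    }
  }
  if (anyNA(band)) {
    bad <- which(is.na(band))[1]
    stop(sprintf(paste0("frequency %.6g cycles/yr (Fourier index j = %d) exceeds ",
                        "the last band's upper bound %g; extend the band spec or ",
                        "shorten the series"),
                 f[bad], j[bad], spec$bands[n_bands(spec), 2]))
  }
  attr(band, "freq") <- f
  band
}

#' Decompose a daily series into frequency-band components
#'
#' Computes the discrete Fourier transform of the series, partitions the
#' Fourier indices into bands with [assign_frequencies()], and
#' inverse-transforms the spectrum masked to each band's indices (with
#' conjugate-symmetric masking, so each component is real). Because the
#' masks partition the spectrum, the K components sum back to the input
#' exactly (up to floating-point roundoff), and components at disjoint
#' Fourier frequencies are empirically uncorrelated on the full grid.
#'
#' @param ts A [daily_series()].
#' @param spec A [band_spec()]; default [default_band_spec()].
#' @return An object of class `band_decomposition`: a list with
#'   `components` (list of K `daily_series`), `source` (the input series),
#'   `spec`, and `band_of_index` (the index-to-band map).
#' @examples
#' t <- 1:1095
#' z <- daily_series(cos(2 * pi * 3 * t / 365))
#' d <- decompose_series(z)
#' sapply(d$components, stats::var) # variance lives in band 1
#' @export
decompose_series <- function(ts, spec = default_band_spec()) {
  stopifnot(is_daily_series(ts))
  n <- length(ts)
  band <- assign_frequencies(n, attr(ts, "days_per_year"), spec)
  K <- n_bands(spec)
  x <- series_values(ts)
  spec_fft <- stats::fft(x)

  # full-length band index per fft bin: bin i (1-based) is index j = i - 1 for
  # j <= n/2, and the conjugate mirror n - j for j > n/2
  j_full <- c(0:(n %/% 2L), if (n %/% 2L + 1L <= n - 1L) (n - ((n %/% 2L + 1L):(n - 1L))))
  band_full <- band[j_full + 1L]

  comps <- vector("list", K)
  total_norm <- sqrt(sum(x^2))
  for (k in seq_len(K)) {
    masked <- spec_fft
    masked[band_full != k] <- 0 + 0i
    comp <- stats::fft(masked, inverse = TRUE) / n
    resid <- max(abs(Im(comp)))
    if (total_norm > 0 && resid > 1e-10 * total_norm) {
      stop(sprintf("imaginary residue %.3g after inverse transform; conjugate symmetry broken", resid))
    }
    comps[[k]] <- series_like(Re(comp), ts)
  }
  structure(list(components = comps, source = ts, spec = spec,
                 band_of_index = band),
            class = "band_decomposition")
}

#' @export
print.band_decomposition <- function(x, ...) {
  K <- length(x$components)
  v <- vapply(x$components, stats::var, numeric(1))
  cat(sprintf("<band_decomposition> %d bands of a %d-day series\n",
              K, length(x$source)))
  for (k in seq_len(K)) {
    cat(sprintf("  band %d [%g, %g) cycles/yr: variance %.4g\n",
                k, x$spec$bands[k, 1], x$spec$bands[k, 2], v[k]))
  }
  invisible(x)
}

#' Reconstruct the source series from a decomposition
#' @param x A `band_decomposition`.
#' @return A `daily_series`: the elementwise sum of the band components.
#' @export
reconstruct <- function(x) {
  stopifnot(inherits(x, "band_decomposition"))
  series_like(Reduce(`+`, lapply(x$components, series_values)), x$source)
}
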