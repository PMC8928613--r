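#' Define a partition of frequencies into bands
#'
#' A `band_spec` is an ordered partition of frequency (in cycles per year)
#' into K contiguous half-open intervals \[low_k, high_k). The default is the
#' six-band partition used in timescale studies of particulate air pollution:
#' band 1 \[1, 6) cycles/yr (seasonal), band 2 \[6, 12) (monthly), band 3
#' \[12, 26), band 4 \[26, 52), band 5 \[52, 104), and band 6 \[104, 183)
#' (acute, fluctuations of roughly 3.5 days or less).
#'
#' Frequencies below the first band's lower bound - including the zero
#' frequency carrying the series mean - have no printed band of their own,
#' yet the decomposition must account for every Fourier index so that the
#' band components sum back to the input. By default they are assigned to
#' band 1; set `include_sub_band_frequencies_in_first = FALSE` to refuse
#' series whose grid produces such frequencies.
#'
#' @param bands A K x 2 numeric matrix (or list of length-2 vectors) of
#'   \[low, high) interval bounds in cycles per year; intervals must be
#'   strictly increasing and contiguous (each upper bound equals the next
#'   lower bound).
#' @param include_sub_band_frequencies_in_first Assign frequencies below the
#'   first lower bound (including the mean) to band 1? Default `TRUE`.
#' @return An object of class `band_spec`.
#' @examples
#' default_band_spec()
#' band_spec(rbind(c(0, 26), c(26, 183)))
#' @export
band_spec <- function(bands, include_sub_band_frequencies_in_first = TRUE) {
  if (is.list(bands)) bands <- do.call(rbind, lapply(bands, as.numeric))
  bands <- as.matrix(bands)
  if (ncol(bands) != 2L || nrow(bands) < 1L || !is.numeric(bands)) {
    stop("'bands' must be a K x 2 numeric matrix of [low, high) bounds")
  }
  if (anyNA(bands) || any(!is.finite(bands))) stop("band bounds must be finite")
  if (any(bands[, 2] <= bands[, 1])) {
    stop("every band must satisfy low < high")
  }
  if (nrow(bands) > 1L) {
    if (any(abs(bands[-nrow(bands), 2] - bands[-1, 1]) > 1e-12)) {
      stop("bands must be contiguous: each upper bound must equal the next lower bound")
    }
  }
  dimnames(bands) <- list(NULL, c("low", "high"))
  structure(list(bands = bands,
                 include_sub_band_frequencies_in_first =
                   isTRUE(include_sub_band_frequencies_in_first)),
            class = "band_spec")
}

#' @rdname band_spec
#' @export
default_band_spec <- function() {
  band_spec(rbind(c(1, 6), c(6, 12), c(12, 26), c(26, 52), c(52, 104), c(104, 183)))
}

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("<band_spec> K = %d bands (cycles per year)\n", n_bands(x)))
  for (k in seq_len(n_bands(x))) {
    cat(sprintf("  band %d: [%g, %g)\n", k, x$bands[k, 1], x$bands[k, 2]))
  }
  if (x$include_sub_band_frequencies_in_first) {
    cat("  frequencies below the first band (incl. the mean) assigned to band 1\n")
  }
  invisible(x)
}

#' @rdname band_spec
#' @export
n_bands <- function(spec) nrow(spec$bands)

#' Read or write a band specification as a YAML config file
#'
#' The file holds a list of `[low, high)` pairs under `bands:` and an
#' optional `include_sub_band_frequencies_in_first:` flag.
#'
#' @param path File path.
#' @param spec A `band_spec` (for writing).
#' @return `read_band_spec` returns a `band_spec`; `write_band_spec`
#'   invisibly returns `path`.
#' @export
read_band_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$bands)) stop("band config must contain a 'bands' list")
  band_spec(cfg$bands,
            include_sub_band_frequencies_in_first =
              if (is.null(cfg$include_sub_band_frequencies_in_first)) TRUE
              else cfg$include_sub_band_frequencies_in_first)
}

#' @rdname read_band_spec
#' @export
write_band_spec <- function(spec, path) {
  stopifnot(inherits(spec, "band_spec"))
  yaml::write_yaml(
    list(bands = lapply(seq_len(n_bands(spec)),
                        function(k) as.numeric(spec$bands[k, ])),
         include_sub_band_frequencies_in_first =
           spec$include_sub_band_frequencies_in_first),
    path)
  invisible(path)
}
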