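Package: freqband
Title: Frequency Band Evaluation of Air Pollution Exposure Prediction Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Timescale-specific evaluation of daily air-pollution exposure
    prediction models. Daily time series are decomposed into frequency bands
    (cycles per year) with a discrete Fourier transform, and model performance
    (Pearson correlation, SD-scaled RMSE, log variance ratio) is computed both
    overall and within each band, so that prediction error at the timescale
    relevant to an epidemiologic study - for example day-to-day variation in
    acute health studies - can be isolated from error at other timescales.
    Also provides a full simulation study linking band-specific classical
    measurement error in predicted PM2.5 to bias and RMSE in acute health
    associations estimated by quasi-Poisson time-series regression with
    natural-spline temporal adjustment, plus CSV input/output, monitor-series
    preprocessing (short-gap interpolation, longest complete run), and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    splines,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
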