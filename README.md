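# freqband

Timescale-specific evaluation of air-pollution exposure prediction models,
for epidemiologists and exposure modellers who need to know whether a
prediction model is good *at the timescale their study uses* — not just
good on average.

## The idea

A time-series study of acute health effects identifies its association from
day-to-day exposure variation. Conventional whole-series metrics comparing a
predicted series `z*(t)` to monitor observations `z(t)` —

* correlation `r = Cor(z*, z)`,
* `RMSE = sqrt(mean((z* - z)^2))`, scaled here by the SD of the reference,
* log variance ratio `LVR = log(Var(z*) / Var(z))`,

— are affected by error at *all* timescales, so they can be overly
pessimistic about a model whose only weakness is its seasonal cycle, and
overly optimistic about one that scrambles daily fluctuations.

`freqband` decomposes both series with a discrete Fourier transform into
components confined to frequency bands (cycles per year; the default
six-band partition ranges from [1, 6) — seasonal — to [104, 183) — acute,
fluctuations of roughly ≤ 3.5 days) and computes the same three metrics per
band. The components sum back exactly to the original series, and error
confined to one band leaves the other bands' metrics untouched.

The package also ships the full simulation study connecting band-specific
classical measurement error to bias and RMSE in estimated acute health
associations: log-normal PM2.5-like series, band-limited error, Poisson
daily health counts, and quasi-Poisson time-series regression with a
280 df/year natural-spline temporal adjustment.

## Worked example

Simulate three years of observed PM2.5 and a prediction carrying strong
(σc = 0.8) classical error confined to the acute band:

```r
library(freqband)
obs  <- simulate_observed(seed = 42)              # z(t) = exp(0.6 x(t) + 1.9)
pair <- make_prediction(obs, error_config(sigma_c = 0.8, error_band = 6), seed = 43)
band_metrics(pair$observed, pair$predicted)
#>      band     r rmse_scaled   lvr
#> 1 overall 0.716       1.036 0.758
#> 2       1 0.975       0.458 0.295
#> 3       2 0.986       0.191 0.151
#> 4       3 0.647       1.040 0.606
#> 5       4 0.398       2.157 1.710
#> 6       5 0.309       2.625 2.028
#> 7       6 0.533       1.567 1.233
```

The overall correlation (0.72) looks moderate, but the acute band tells the
real story for a short-term health study: r = 0.53 and a scaled RMSE half
again the band's own variability. Bands 1–2, where no error was added, stay
near-perfect (the small departure from identity is exponentiation leakage:
error added on the log scale becomes multiplicative on the concentration
scale). Bands 3–5 carry almost no signal in this simulation, so their
metrics are dominated by that leakage.

The full study — 24 error conditions × replicates, health-count simulation,
association fits, and the R² table relating each performance metric to
health-association bias and RMSE — is one call:

```r
st <- run_study(n_replicates = 25, seed = 1)
st$r2          # R-squared per (health measure, metric, scope)
st$conditions  # per-condition means, bias, health RMSE
```

Real monitor/prediction CSV pairs are evaluated with the same machinery,
including short-gap interpolation (< 10 missing days) and longest
complete-run extraction:

```sh
Rscript exec/freqband evaluate --observed monitor.csv --predicted model.csv
```

(`decompose`, `simulate`, `reproduce-study`, and `fixtures` subcommands are
also available; see `?freqband_cli`.)

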