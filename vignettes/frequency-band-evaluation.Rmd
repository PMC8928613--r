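---
title: "Frequency band evaluation of exposure prediction models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency band evaluation of exposure prediction models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(freqband)
```

## The problem

Air-pollution prediction models (statistical fusions, machine-learning
surfaces, chemical transport models) are usually judged by whole-series
metrics: Pearson correlation $r$, RMSE, or the log variance ratio
$\mathrm{LVR} = \log(\mathrm{Var}(z^\ast)/\mathrm{Var}(z))$ between a
predicted series $z^\ast(t)$ and monitor observations $z(t)$. Those
metrics mix error at all timescales. A time-series study of *acute*
health effects, however, identifies its association almost entirely from
day-to-day exposure variation: a model that tracks the seasonal cycle
beautifully but scrambles the daily fluctuations can look excellent
overall while being useless for the study, and vice versa.

`freqband` evaluates predictions *per timescale*. Both series are
decomposed with a discrete Fourier transform into components confined to
frequency bands (in cycles per year), and the three metrics are computed
band by band. The package also contains the full simulation machinery to
quantify how band-specific measurement error propagates into bias and
RMSE of estimated acute health associations.

## Band decomposition

For a gap-free daily series of length $n$, Fourier index
$j \in \{0,\dots,\lfloor n/2 \rfloor\}$ carries frequency
$f_j = j \cdot d / n$ cycles per year, where $d$ is `days_per_year`.
The default partition is the six-band scheme used in timescale studies
of particulate matter: $[1,6)$ (seasonal), $[6,12)$ (monthly),
$[12,26)$, $[26,52)$, $[52,104)$, and $[104,183)$ cycles per year
(acute, fluctuations of about 3.5 days and shorter). Each band's
component is the inverse transform of the spectrum masked to that band's
indices (conjugate-symmetrically, so components are real), hence the
components sum back to the original series and their variances partition
its variance.

Two conventions deserve comment, because any implementation must pick
them:

* **Sub-band frequencies.** The printed bands start at 1 cycle/yr, but
  the reconstruction identity needs every index — including $j = 0$,
  the mean — to belong to some band. By default everything below the
  first band's lower bound joins band 1; a flag on `band_spec()` refuses
  such grids instead, for users who want the strict printed partition.
* **Boundaries.** Intervals are half-open $[low, high)$, so an index
  sitting exactly on a boundary goes to the upper band. With
  `days_per_year = 365` (the default) and $n = 1095$, integer
  cycles-per-year frequencies are exact Fourier frequencies, which keeps
  the simulation's band assignments crisp. The top bound of 183
  cycles/yr covers the Nyquist frequency of any daily grid
  ($\le 182.5$ cycles/yr at 365 days/yr).

`decompose_series()` enforces that residual imaginary parts after the
inverse transform stay below $10^{-10}$ of the signal norm; anything
larger would indicate broken conjugate symmetry and is an error rather
than something to discard silently.

## Performance metrics

`overall_metrics()` and `band_metrics()` report, per comparison:
$r = \mathrm{Cor}(z^\ast, z)$,
$\mathrm{RMSE} = \sqrt{\tfrac1n \sum_t (z^\ast(t) - z(t))^2}$ scaled by
the standard deviation of the reference series (or its band component),
and the LVR. Sample statistics use the $n-1$ denominator; the RMSE
itself averages with $1/n$ as printed above. Scaling the RMSE by the
reference SD makes overall and band values comparable: each answers
"how large is the error relative to the variability this band actually
has?".

A correlation against a constant prediction is undefined and reported as
`NA` (with $\mathrm{LVR} = -\infty$); a constant *reference* is an error
for the overall metrics, but inside `band_metrics()` a band whose
reference variance is below $10^{-20}$ of the total is reported as `NA`
rather than failing the call — real series routinely carry no energy in
some bands, and the alternative is metrics computed on floating-point
leakage.

## The simulation study

### Observed exposure

`simulate_observed()` builds a standardized log-scale signal
$x(t)$ from band-limited cosine sums in bands 1, 2 and 6 (seasonal,
monthly, acute), then exponentiates:
$z(t) = \exp(x(t)\,\sigma_x + \mu_x)$ with defaults
$\mu_x = 1.9$ and $\sigma_x = 0.6$ log µg/m³, reflecting log PM2.5
concentrations in a large US city; three years of daily data
($n = 1095$). Each band component is an equal-amplitude sum of cosines
at every integer cycles-per-year frequency inside the band (1–5, 6–11,
104–182), each with an independent uniform random phase, standardized to
its target variance; the summed signal is standardized to unit sample
variance. Equal amplitudes with random phases fill the band's support
and give genuine series-to-series variability across replicates while
keeping the spectral envelope flat — the simplest construction
consistent with "cosines of varying wavelengths within the band". The
seasonal sensitivity analysis raises the band-1 variance to $1.5^2$ or
$2^2$ (bands 2 and 6 stay at 1) with the total still standardized to 1,
which *shrinks* the acute band's variance share.

### Predictions with band-limited classical error

`simulate_band_error()` draws iid standard normal noise, extracts one
band by DFT, and standardizes it to unit variance; `make_prediction()`
then forms $x^\ast(t) = x(t) + w_k(t)\,\sigma_c$ and
$z^\ast(t) = \exp(x^\ast(t)\,\sigma_x + \mu_x)$, classical error
confined to band $k$ on the log scale with magnitude
$\sigma_c \in \{0.2, 0.4, 0.6, 0.8\}$. On the log scale the confinement
is exact; on the concentration scale exponentiation leaks a small amount
of error into other bands (the error becomes multiplicative), which is
visible as slightly sub-identity metrics in error-free bands. Metrics in
the study are computed on the concentration scale, since that is the
scale on which models are compared in practice.

One standardized error series is drawn per replicate and band and reused
across the four magnitudes, so the magnitude grid varies only
$\sigma_c$.

### Health counts and the association model

Daily counts are Poisson with
$\mu(t) = \exp(\beta_0 + \beta_1 z^{\mathrm{res}}(t) + 0.03\, z^{\mathrm{fit}}(t))$,
where the fitted/residual split comes from an OLS regression of $z(t)$
on a 24-df natural spline of the day index (`split_exposure()`; about
8 df/yr, i.e. seasonal-plus-monthly smoothness — the residual carries the
acute variation). Defaults: $\beta_0 = 5$ (about 200 counts/day, the
scale of cardiorespiratory ED visits in a large city) and
$\beta_1 = \log(1.1)/10$, relative risk 1.1 per 10 µg/m³. Exposure
enters in µg/m³, matching that calibration.

`fit_health_association()` is a quasi-Poisson regression of counts on
the predicted exposure plus a natural spline of time with 280 df per
year — deliberately enormous, so that error added at up to 104 cycles/yr
is absorbed by the adjustment and only acute variation identifies
$\beta_1$. Fitting uses iteratively reweighted least squares with the
normal equations and a Cholesky solve on a QR-orthogonalized basis; the
coefficients equal plain Poisson maximum likelihood (the dispersion,
Pearson $\chi^2/\mathrm{df}$, rescales the SE only), and the test suite
verifies agreement with `stats::glm(family = quasipoisson())` to
$10^{-8}$ on the coefficient. Convergence is a relative deviance change
below $10^{-8}$, at most 25 iterations; non-converged fits are flagged
and dropped from aggregation with a warning. The 841-column adjustment
basis depends only on the grid and is built once per study
(`health_spline_basis()`), which is what makes the 600-fit study run in
minutes.

Counts are simulated once per replicate (they depend only on the
observed series) and reused across the 24 prediction conditions.

### Aggregation

`summarize_condition()` computes, per condition, the percent relative
mean bias $100 \cdot \overline{(\hat\beta_1 - \beta_1)} / \beta_1$ and
the health association RMSE
$\sqrt{\overline{(\hat\beta_1 - \beta_1)^2}}$, plus arithmetic means of
every performance metric. `association_r2()` then fits one straight
line of each health measure on each condition-mean metric across the
24 conditions and reports $R^2$ — condition means, not replicate-level
points, because the study's claim is about how condition-level model
quality predicts condition-level estimation capacity.

## Problem sizes and reproducibility

The default study (`run_study()`) uses 25 replicates, the package's
desk-scale configuration; `scripts/acceptance.R` runs 100 replicates,
the full study scale. The parameter-recovery check in the test suite
uses 100 replicates: the per-fit Monte-Carlo SE of $\hat\beta_1$ is
about 10% of $\beta_1$, so averaging over 100 replicates is needed to
resolve biases of a percent or two. All randomness flows from one
master seed through a counter-based child-seed derivation
(per replicate and purpose), so studies are bitwise reproducible and
observed-series, count, and error streams are mutually independent.

## What the generator does and does not emulate

The synthetic series match real urban PM2.5 in marginal distribution
(log-normal, median $e^{1.9} \approx 6.7$ µg/m³), in timescale
composition (seasonal/monthly/acute energy), and in the magnitude of
acute health associations. They do **not** contain meteorological
confounding, missing days, Berkson-type or spatially structured error,
long-memory behaviour, or energy in bands 3–5; passing tests therefore
demonstrate correctness of the method and its implementation under
band-confined classical error, not performance guarantees for any
particular real prediction model. Real-series evaluation
(`evaluate_files()`, the `evaluate` CLI subcommand) applies the same
metrics after gap interpolation (linear, for runs of fewer than 10
missing days) and extraction of the longest complete run of at least a
year — the package's preprocessing mirror of standard monitor-data
practice.

## Known limitations

* Daily, gap-free grids only; no irregular-sampling spectral methods.
* No wavelet or spatial (two-dimensional Fourier) decompositions.
* The DFT treats the series as circular; no tapering or detrending is
  applied beyond band 1 absorbing the mean. For series with strong
  trends the lowest band conflates trend and seasonal variation.
* The quasi-Poisson health model adjusts for time only; applying it to
  real data would additionally require meteorological confounders.
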