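---
title: "Combining seasonal ARIMA and per-weekday exponential smoothing for daily outpatient visits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combining seasonal ARIMA and per-weekday exponential smoothing for daily outpatient visits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Daily outpatient volume at large hospitals is dominated by a weekly cycle:
clinic schedules repeat on a 7-day rota, weekend volumes collapse, and the
counts for, say, Thursdays across successive weeks form a slowly drifting
sub-series of their own. On top of the cycle sit autocorrelated day-to-day
noise, mild annual seasonality, and public-holiday "singularities" — isolated
days whose volume says nothing about routine demand. Staff rostering and
capacity planning need the next week's seven daily counts, one week ahead.

`visitcast` forecasts such a series with two complementary arms and a
per-weekday convex combination of them:

* **Arm 1 — seasonal ARIMA on the daily series.** The series $x_t$ is made
  stationary by one seasonal difference at lag 7, $w_t = (1 - B^7)\,x_t$, and
  $w_t$ is modelled as a *subset* ARMA
  $$\varphi(B)\, w_t = \Theta(B)\, \varepsilon_t, \qquad
    \varphi(B) = 1 - \textstyle\sum_k \varphi_k B^k,\quad
    \Theta(B) = 1 - \textstyle\sum_k \theta_k B^k,$$
  where only a sparse set of lags carries coefficients. This captures the
  linear autocorrelation and cyclicity of the daily process.
* **Arm 2 — single exponential smoothing (SES) per weekday.** Re-indexing the
  data as $x_{t',\tau}$ (week $t'$, weekday $\tau$) gives seven weekly
  sub-series; each is smoothed by
  $$\hat x^2_{t'+1,\tau} = \alpha\, x_{t',\tau} + (1-\alpha)\,\hat x^2_{t',\tau},$$
  which tracks the non-linear drift of each weekday's level — the
  day-of-week effect — without imposing a linear model.
* **Combination.** For each weekday the two one-week-ahead predictions are
  mixed as $\hat x_{t',\tau} = l_1 \hat x^1 + l_2 \hat x^2$ with
  inverse-error-energy weights
  $$l_i = \frac{E_i^{-1}}{E_1^{-1} + E_2^{-1}}, \qquad
    E_i = \sqrt{\textstyle\sum_j e_{ij}^2},$$
  where the $e_{ij}$ are arm $i$'s one-step training residuals restricted to
  that weekday. The weights are positive and sum to one, so the combined
  forecast always lies between the two arms.

The daily and weekly indexings are aligned by $t = 7(t'-1) + \tau$, the
bijection implemented in `daily_index()`; the combination is carried out
weekday by weekday, so the daily arm's seven forecasts are matched to the
seven smoothers through this mapping.

## Preprocessing

Holiday singularities are detected per weekday: a cell is flagged when it
falls outside two sample standard deviations (denominator $n-1$) of its
weekday's mean, both computed over *all* weeks of the training window — the
method is purely statistical and uses no holiday calendar. Flagged cells are
replaced by the mean of the same weekday in the adjacent weeks (the single
existing neighbour at the panel edges), in one pass using original neighbour
values throughout; the fixed replacement counts such a rule produces would
change under iterated re-detection, which is why a single pass is used.
Detection statistics include the flagged value itself; with a 2-SD band and
realistic panel lengths this is conservative (a lone spike still exceeds the
band it inflates, while two large adjacent spikes on the same weekday can
mask each other — a known limitation of variance-based outlier rules).

Preprocessing is applied to the training window only, at every rolling
origin. Observed test values are never modified: evaluation must be against
real demand, holidays included.

## Estimation choices

* **Conditional least squares.** The subset-ARMA objective is the
  conditional sum of squared innovations: presample innovations are zero and
  the recursion conditions on the first $\max(\text{AR lags})$ observations.
  Minimisation is BFGS from a zero start (`stats::optim`), with standard
  errors from the numerical Hessian, $\widehat{\mathrm{Var}} = 2\hat\sigma^2
  H^{-1}$. Exact maximum likelihood is deliberately out of scope; at the
  sample sizes involved (hundreds of days) the two differ negligibly, and
  conditional least squares keeps the estimator transparent and fast. A
  diverging objective (non-invertible MA region) is clamped to a large
  finite value so the line search retreats; an AR root on or inside the unit
  circle is recorded as a warning on the model rather than an error.
* **Order selection.** Full contiguous grids $p \le p_{\max}$,
  $q \le q_{\max}$ are scored by
  $\mathrm{BIC} = n \ln(\mathrm{RSS}/n) + k \ln n$ with $k = p + q + 1$
  (the innovation variance counts as a parameter; additive constants are
  dropped as they move no argmin). $n$ is each candidate's own effective
  sample size after conditioning. Ties break toward smaller $p+q$, then
  smaller $p$. Sparse lag sets then arise by **significance pruning**: the
  smallest $|t|$ below 1.96 is dropped and the model refitted, repeatedly.
  1.96 is the two-sided 5% normal cutoff; the threshold is a tunable
  (`t_threshold`).
* **Differencing convention.** "One seasonal difference at lag 7" is the
  default (`diff_spec(d = 0, D_order = 1, D_lag = 7)`). A regular first
  difference can be added with `d = 1` for strongly trending series; both
  operators and their inversion are implemented generally via the
  differencing polynomial.
* **SES initialisation and $\alpha$.** The initial level is the mean of the
  first three weeks. $\alpha$ is chosen on the grid $0.01, 0.02, \ldots,
  0.99$ by minimum one-step MSE, with ties broken by smaller MAPE and then
  smaller $\alpha$ — a single total order over the dual MSE/MAPE criterion.
  One-step errors are scored from week 4 onward so the initialisation window
  does not score itself. The 0.01 grid resolution is finer than the
  precision at which a smoothing constant is practically distinguishable on
  forty-odd weekly observations.
* **Ljung–Box diagnostics** default to lags $\{6, 12, 18, 24\}$ (capped in
  practice by the residual length), with degrees of freedom $m - k$ floored
  at 1.

## The rolling driver

`rolling_forecast()` advances an expanding origin over the test weeks. At
each origin it (1) preprocesses the training window, (2) refits both arms —
ARIMA lag sets are selected (BIC + pruning) at the *first* origin and frozen
afterwards, coefficients re-estimated every origin; the SES $\alpha$ is
re-optimised per origin by default (`refit_alpha = FALSE` freezes it), —
(3) recomputes the per-weekday weights from the training residuals of the
current window (an expanding in-sample window; past *test* residuals are not
recycled into the weights), and (4) emits seven records with the observed
value and all three predictions. Freezing the lag structure reflects how the
model form would be fixed once at deployment while coefficients track new
data.

Two degenerate-case rules matter in practice:

* If **both** arms fit a weekday exactly (zero residual energy each — e.g. a
  noise-free weekly cycle), the inverse-energy formula is undefined and the
  driver assigns equal weights: any convex combination of two exact
  forecasts is exact. `combine_weights(0, 0)` itself still errors, since
  outside this pipeline context the situation signals a degenerate fit.
* A weekday with one zero-energy arm gives that arm weight one.

Forecasts are not clipped or rounded by default (`clip_zero` floors the
combined forecast at zero for presentation); predicted values are
real-valued even though observations are counts.

## Evaluation

`build_report()` computes, per model, the overall MAPE (the mean of *all*
per-day absolute percentage errors — not the mean of the sub-MAPEs), the
workday (weekdays 1–5) and weekend (6–7) MAPEs, per-weekday APE sequences,
and the residual mean and SD. MAPE is undefined at a zero observed count;
the default is to raise an error, and `skip_zero_days = TRUE` drops such
days explicitly, because silently changing the denominator set materially
changes the reported numbers.

## The synthetic generator

Real outpatient ledgers are rarely shareable, so `generate_series()` builds
series with the structure the method assumes:

$$x_t = \mathrm{round}\,\max\!\Big(0,\; \mu_\tau (1 - \text{dep}_t)
  + \beta t' + A \sin(2\pi t / 365) + \eta_t\Big),\qquad
  \eta_t = \phi\,\eta_{t-1} + N(0, \sigma^2),$$

i.e. a weekday profile with weekend troughs, optional linear trend and mild
annual cycle, AR(1) noise, and holiday depressions on chosen days. The
bundled presets use 51-week series (one trimmed calendar year) with a
43-week training / 8-week test split. The `eov_like` preset takes its
weekday profile (206, 193, 182, 171, 150, 86, 34) from the observed test
week of the bundled worked example, innovation SD 15, AR coefficient 0.5,
annual amplitude 10 and a handful of holiday depressions — values a
practitioner would call typical for a specialty clinic averaging ~150
visits/day; the `rov_like` preset does the same for the lower-volume
respiratory-style profile. `generate_ses_truth()` produces local-level
panels whose optimal one-step smoother has a known $\alpha$, for parameter
recovery tests.

What the generator does **not** emulate: over-dispersed count noise
(innovations are Gaussian, not Poisson/negative-binomial), slowly varying
weekday profiles, epidemic surges, or calendar-linked holiday clustering.
Tests passing on synthetic data therefore demonstrate the pipeline's
correctness and its statistical behaviour under the assumed structure, not
performance on any particular hospital's data.

A note on sampling variability: recovering the SES constant from a single
40-week weekday series has an estimator SD of roughly 0.12, so recovery
assertions are made on the mean across the seven independent weekday series
(SD ≈ 0.045), not pointwise.

## Problem sizes and determinism

The test-suite and acceptance runs use 51-week series, order search on
grids up to $p_{\max} = 3$, $q_{\max} = 7$ ($q_{\max} = 7$ is needed to
reach the weekly moving-average lag after seasonal differencing; larger
grids change nothing on weekly-cyclic series while multiplying fit count),
coefficient-recovery simulations at $n = 3000$, and 500-replicate
white-noise calibration of the Ljung–Box test. Every stochastic step is
seeded; reruns under the same seed are byte-identical, including written
CSVs.

## Worked example

The package ships a reference worked example (one test week for an
endocrinology and a respiratory outpatient series, with both arms'
predictions and the combination weights). `cmd_replicate_week45()` checks
that the evaluation module reproduces its internally consistent error
figures — ARIMA-arm MAPE 19.31%, SES-arm 19.55% (endocrinology) and SES-arm
21.90% (respiratory), and a Monday combined APE of 5.09%. The example's
respiratory ARIMA MAPE as published does not recompute from its own rows
(we obtain 24.52%); it is documented here and asserted nowhere.

```{r}
library(visitcast)
cmd_replicate_week45()

series <- generate_series(scenario_preset("eov_like"))
records <- rolling_forecast(series, rolling_config(train_weeks = 43))
build_report(records, skip_zero_days = TRUE)
```

## Known limitations

* Two arms only; no regret-based or time-varying weighting.
* No multiplicative seasonal polynomials, exact-likelihood estimation, or
  Box–Cox transforms.
* The 2-SD singularity rule can mask paired outliers (see above) and has no
  calendar awareness.
* MAPE-based evaluation is undefined at zero counts and asymmetric around
  over-/under-prediction; it is used here because it is the standard
  indicator in this application area.
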