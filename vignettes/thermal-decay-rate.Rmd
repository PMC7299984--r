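---
title: "The thermal decay rate index: model, estimator, and pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The thermal decay rate index: model, estimator, and pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermdecay)
```

## The model

Vegetation buffers the diurnal swing of land surface temperature (LST):
dense stands with large thermal mass heat and cool slowly, sparse cover and
bare soil swing fast. After the early-afternoon temperature peak, cooling of
the land surface is dominated by conductive and convective heat exchange
with its surroundings, for which Newton's law of cooling applies:

$$\frac{dT}{dt} = -k\,(T - T_a), \qquad
  T(t) = T_a + (T_0 - T_a)\,e^{-kt},$$

with $T_0$ the temperature at the start of cooling, $T_a$ the ambient
temperature cooled toward, and $k$ the thermal decay rate. Physically
$k = \alpha_{tot} / (\rho\, c\, V\!/\!A)$ — the effective heat transfer
coefficient over the thermal mass — so denser, wetter, more voluminous
vegetation implies a *smaller* decay rate ([`theoretical_rdk()`]).

Polar-orbiting satellites observe each location twice daily at fixed local
times, once near the diurnal maximum and once at night. Writing the day
observation as $T_d$ cooling toward the night observation $T_n$ over
$\Delta t$ hours, and assuming $T_a \ll T_d$ so the ambient term can be
dropped, the per-pair estimator is

$$\hat{R}_{dk} = \frac{\ln(T_d / T_n)}{\Delta t},$$

and the annual index $\bar{R}_{dk}$ is its arithmetic mean over the valid
pairs of a year ([`rdk_estimate()`], [`rdk_annual()`]). The logarithm is
natural: the estimator is the algebraic inversion of $e^{-k\Delta t}$, and
any other base would break the inversion. Temperatures must be in Kelvin —
the estimator works on the day/night *ratio*, which is meaningless on an
interval scale — and ingest refuses values below 150 K as almost certainly
Celsius or unscaled integer products.

### The bias of dropping the ambient term

Dividing the cooling solution by $T_0$,

$$\frac{T(t)}{T_0} = e^{-kt} + \frac{T_a}{T_0}\left(1 - e^{-kt}\right),$$

the estimator ignores the second term. When $T_a = 0$ the estimator is
*exact*; for $T_a > 0$ it understates $k$, increasingly so as $T_a/T_0$
grows. [`approximation_bias()`] quantifies this in closed form, and the test
suite verifies that end-to-end recovery error on simulated scenes equals
that closed form to $10^{-12}$. In practice this bias is large in absolute
terms (with $T_a \approx 285\,$K and $T_d \approx 310\,$K most of the
signal is suppressed), but it is a smooth monotone transform of the true
$k$ at fixed $T_a$, $T_0$: rankings and trends — the quantities the index
is used for — are preserved, which the rank-correlation invariant tests
make explicit.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `delta_t` | 12 | hr | Aqua 13:30→01:30 and Terra 10:30→22:30 both span 12 h |
| `min_pairs` | 10 | pairs/yr | 8-day composites give ≤46 pairs; fewer than 10 makes a noisy annual mean |
| `min_n` | 10 | years | trend tests on a 15-year record need most years present |
| `p_high`, `p_moderate` | 0.05, 0.1 | — | the two conventional significance bands of the 5-class trend map |
| `map_threshold` | 100 | mm/yr | aridity mask; kept *strictly* above threshold |
| `noise_sd` | 1 | K | typical satellite LST retrieval error, applied in the temperature domain |

Warm nights ($T_n > T_d$, e.g. advection or retrieval error) produce a
negative rate. The value is returned rather than clamped, a flag and the
flagged fraction are reported, and `mask_warm_nights = TRUE` excludes them
— both behaviors are defensible and the choice is left to the analyst.

## The scene simulator

[`make_scene()`] is a forward model of everything the pipeline consumes:

* a **true decay field** `truth_k` on a smooth spatial gradient (default
  0.005–0.03 hr⁻¹), standing in for a vegetation-density gradient. The
  field is a deterministic function of the scene parameters, so changing
  the seed changes noise and clouds but never the ground truth;
* a **diurnal cycle** per pixel: exponential cooling from the 13:30 peak
  (310 K default) toward the ambient temperature (285 K default) until
  dawn (06:00), then a half-sinusoid heating branch back to the peak. The
  cooling branch is the physics under test; the heating branch is a
  pluggable stand-in whose only load-bearing property is that the
  mid-morning Terra overpass samples below the early-afternoon Aqua
  overpass. No quantitative result in the package depends on its exact
  shape;
* **overpass sampling** at Aqua (13.5/1.5) or Terra (10.5/22.5) local
  hours, 46 composites per year over 2003–2017 by default;
* **observation noise**: additive zero-mean Gaussian on temperatures
  (σ = 1 K default), not on rates, because satellite LST error lives in
  the temperature domain;
* **clouds**: per-date independent Bernoulli masking of day and night
  *jointly*, matching how day/night pairs are composited together;
* **trends**: a per-year additive slope on `truth_k`, scalar or gridded.

What the simulator deliberately does not emulate: sun-angle geometry,
topography, radiative transfer, seasonality of the ambient temperature,
freezing conditions and fires, and spatially correlated cloud fields.
Passing tests therefore demonstrate the estimator and statistics are
implemented correctly and calibrated under the stated noise model — not
that the index is unbiased on real MODIS retrievals, where the
constant-ambient assumption is only approximate.

For power analyses the injected trend is expressed against the annual-mean
noise floor: with σ = 1 K, 46 composites and ~305 K temperatures, the
annual $\bar{R}_{dk}$ noise is ≈ 6×10⁻⁵ hr⁻¹, and the calibrated
detection check uses a slope of 0.3 σ per year, where Mann–Kendall power
at n = 15 comfortably exceeds 90%.

## The statistical layer

**Mann–Kendall** ([`mann_kendall()`]): $S = \sum_{i<j}\mathrm{sign}(x_j -
x_i)$, variance with the standard tie correction, Z with the ±1 continuity
correction (applied by default — standard practice at n = 15, and
exposed as a toggle), two-sided p from the normal approximation (both
trend directions are mapped, so a one-sided test would be wrong).
Classification into five classes (`increasing_p05` … `decreasing_p05`)
uses p < 0.05 and 0.05 ≤ p < 0.1 bands; for $\bar{R}_{dk}$ an increasing
class is interpreted as decreasing vegetation, and `invert = TRUE` recodes
accordingly. No multiple-testing adjustment is applied across pixels —
per-pixel raw significance is what the conventional maps display — and
per-pixel series shorter than `min_n` years yield a missing class rather
than an error.

**RMA regression** ([`rma_regression()`]): slope
$\mathrm{sign}(r)\,\sigma_y/\sigma_x$, intercept $\bar y - b\bar x$.
Chosen over ordinary least squares for platform comparison because both
measurements carry error and the fit must be symmetric (axis swap inverts
the slope exactly).

**Correlation tables** ([`correlation_table()`]): Pearson and Spearman over
pairwise-complete pixels (variables from different periods or masks retain
their common support), entries with fewer than 3 joint pixels are missing,
and latitude-like variables can be folded to absolute value. The
precipitation mask keeps pixels strictly above 100 mm/yr.

## Numerical and design choices

* Missing values are `NA` everywhere, never 0; aggregation functions count
  what they drop (`n_pairs`, `warm_night_frac`, retained-pixel counts).
* Grids are pixel-center registered, row 1 north, stored row-major in
  files; the convention is asserted by the round-trip tests.
* Raster files are ESRI ASCII grids written with 17 significant digits, so
  write→read round trips are bit-lossless for doubles; the CRS label
  travels in a `.prj` sidecar.
* Regridding: nearest-neighbor for coarse→fine, block mean of valid pixels
  for fine→coarse; `"auto"` chooses by comparing cell sizes. Block means
  conserve the global mean exactly on aligned integer-factor grids.
* Annual grouping is by calendar year of the composite start date.
* Ties in Mann–Kendall reduce the variance; a wholly constant series gets
  S = 0, Z = 0, p = 1.
* `make_scene()` floors trended decay constants at 10⁻⁶ hr⁻¹ so a strong
  negative trend cannot produce a non-physical non-positive rate.
* Specific heat in `theoretical_rdk()` is an opaque positive factor; the
  function enforces positivity and the exact reciprocal/linear scalings,
  not unit algebra.

## Problem sizes used by the test suite

The identity and ordering checks run on 100×100 and 40×40 single-year
scenes with 46 composites; calibration uses 10,000 null series and 2,000
trended series of length 15; the oracle equivalence check uses 1,000
random series up to n = 50. These sizes keep the full suite under half a
minute while leaving the binomial tolerances comfortably tight.

## Known limitations

* The estimator's absolute scale is compressed whenever $T_a$ is not
  negligible; treat $\bar{R}_{dk}$ as an index (ranks, trends,
  correlations), not a physical rate constant.
* The normal approximation for Mann–Kendall is used down to `min_n = 10`;
  exact permutation p-values are not implemented.
* Regridding assumes both grids share one coordinate system; no datum
  reprojection is attempted.
* Cross-composite day/night pairing is unsupported: a date contributes
  only when both roles are present.
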