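# thermdecay

Vegetation buffers the day–night swing of land surface temperature (LST):
dense, wet, voluminous canopies have large thermal mass and cool slowly
after the afternoon peak; sparse cover and bare soil cool fast. `thermdecay`
turns that physics into a vegetation index. It estimates the **thermal decay
rate** from paired day/night satellite LST under Newton's law of cooling,

```
T(t) = T_a + (T_0 - T_a) e^(-k t)        (cooling toward ambient T_a)
R_dk = ln(T_day / T_night) / Δt          (per-pair estimator, hr⁻¹)
R̄_dk = mean of R_dk over a year's valid pairs
```

with the theoretical link `k = α_tot / (ρ c V/A)`: the larger the thermal
mass, the smaller the decay rate. The package is aimed at land-surface and
vegetation remote-sensing analysts who want to compute R̄_dk maps from
day/night LST stacks (MODIS Aqua/Terra-style sampling) and run the
surrounding analysis:

* per-pixel annual R̄_dk maps with valid-pair accounting and warm-night
  flagging (`rdk_annual()`, `rdk_annual_map()`);
* the closed-form bias of the estimator when the ambient temperature is not
  negligible (`approximation_bias()`);
* grid plumbing: lossless plain-text (ESRI ASCII grid) raster I/O,
  nearest-neighbor downscaling / block-mean upscaling, precipitation
  threshold masking (`read_ascii_grid()`, `regrid()`, `mask_by_threshold()`);
* statistics: tie-corrected Mann–Kendall trend tests with 5-class
  significance mapping, reduced major axis regression for cross-platform
  comparison, Pearson/Spearman cross-correlation tables
  (`mann_kendall()`, `trend_map()`, `rma_regression()`,
  `correlation_table()`);
* a Newtonian diurnal-cooling scene simulator with Aqua/Terra overpass
  sampling, temperature noise, joint day/night cloud masking, and injected
  multi-year trends, so the whole pipeline is testable without satellite
  downloads (`make_scene()`);
* a command-line pipeline (`exec/rdk`) with verbs `simulate`, `annual-rdk`,
  `trend`, `correlate`.

All user-facing functions take data frames or raster stacks and return
tibbles or stacks; fitted objects support `tidy()`/`glance()` and results
plot via `autoplot()`.

## Worked example

A single pair 12 h apart:

```r
library(thermdecay)
rdk_estimate(t_day = 300, t_night = 290)
#> [1] 0.002825129
```

300 K cooling to 290 K over 12 h implies a decay rate of ~2.8×10⁻³ hr⁻¹.
Now a full simulated record — 20×20 pixels, 15 years × 46 composites of
Aqua-like sampling with 1 K noise and 10% clouds, with a decay-rate
increase (vegetation loss) injected into the left half of the scene:

```r
scene <- make_scene(n_rows = 20, n_cols = 20, years = 2003:2017,
                    n_composites = 46, noise_sd = 1, cloud_fraction = 0.1,
                    trend_slope = matrix(rep(c(3e-4, 0), each = 200), 20, 20),
                    seed = 42)
stacks <- scene_stacks(scene)
annual <- rdk_annual_map(stacks$day, stacks$night, delta_t = 12, min_pairs = 10)
annual$rdk
#> <raster_stack> rdk [1/hr]: 20 x 20 pixels, 15 layer(s)
#>   grid 20x20@1(0,0); 100.0% valid
#>   layers: 2003, 2004, 2005 ... 2017

trend_map(annual$rdk, min_n = 10)$counts
#> # A tibble: 5 × 2
#>   class              n
#>   <fct>          <int>
#> 1 decreasing_p05     6
#> 2 decreasing_p10     3
#> 3 none             187
#> 4 increasing_p10     3
#> 5 increasing_p05   201
```

The 200 trended pixels are recovered as significant increasing decay-rate
trends (p < 0.05) — read as vegetation decline — while the flat half shows
detections near the nominal false-positive level. Comparing the year-one
map against the simulator's ground truth:

```r
fit <- rma_regression(tibble::tibble(truth = as.vector(scene$truth_k),
                                     recovered = as.vector(stack_layer(annual$rdk, 1))),
                      truth, recovered)
glance(fit)
#> # A tibble: 1 × 4
#>    slope intercept pearson_r     n
#>    <dbl>     <dbl>     <dbl> <int>
#> 1 0.0679 0.0000872     0.985   400
```

The recovered index is almost perfectly rank-correlated with the true
decay field (r = 0.985) but compressed in scale (RMA slope 0.068): with a
285 K ambient temperature the estimator's small-ambient approximation
suppresses the absolute magnitude while preserving ordering and trends —
exactly the bias `approximation_bias()` predicts. Treat R̄_dk as an index,
not a physical rate constant.

The same run from the shell:

```sh
rdk simulate   --out-dir scene --n-rows 20 --n-cols 20 --seed 42 --noise-sd 1 --cloud-fraction 0.1
rdk annual-rdk --manifest scene/manifest.csv --out-dir annual
rdk trend      --rdk-dir annual --out-dir trend
```

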