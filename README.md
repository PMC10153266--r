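# remispeckle

Quantitative blood-flow mapping from multi-exposure laser speckle contrast
imaging (MESI), with a fast quasi-analytic per-pixel estimator.

## The problem

Laser speckle contrast imaging infers perfusion from the blur of a laser
speckle pattern: the squared contrast `K² = (σ/Ī)²` of a time-integrated
speckle image falls with exposure time `T` at a rate set by the correlation
time `τ_c` of the scattered field, and `1/τ_c` tracks blood flow. A single
exposure cannot separate flow from static scattering or optical
normalization, so MESI records `K²` at many exposures and fits, per pixel,

```
K²(T) = (1 − D_MU) · K²_ves(T) + D_MU · K²_par(T)

K²_ves = β [ ρ² (e^(−2x) − 1 + 2x) / (2x²)
           + 4ρ(1−ρ) (e^(−x) − 1 + x) / x² + (1−ρ)² ],        x = T/τ_c

K²_par = β [ ρ² (e^(−2√x)(4x + 6√x + 3) + 2x − 3) / (2x²)
           + 8ρ(1−ρ) (e^(−√x)(2x + 6√x + 6) + x − 6) / x² + (1−ρ)² ]
```

with `β` the speckle normalization, `ρ` the dynamic-scattering fraction,
and `D_MU` the weight between multiple-ordered scattering (vessels) and
multiple-unordered scattering (parenchyma). Per-pixel nonlinear
least-squares fitting of this model is accurate but far too slow for live
viewing.

This package implements, in pure R:

* the closed-form forward models and their semilogarithmic derivatives
  (`k2_vessel()`, `k2_parenchyma()`, `k2_mixed()`, `dk2_dlnT()`,
  `k2_crit()`);
* sliding-window contrast computation from raw frames
  (`compute_contrast()`);
* a reference bounded least-squares fitter (`fit_simple()`,
  `fit_mixed()`);
* the quasi-analytic estimator — filter the `K²(ln T)` curves, locate the
  derivative peak, extrapolate the exposure-time limits through boundary
  ratio responses, assign the scattering model from the peak amplitude, and
  interpolate `τ_c` at the critical contrast — plus a spatially
  regularized variant that smooths the `β` map (`remi_pipeline()`);
* a synthetic-data simulator with exact ground truth
  (`simulation_grid()`, `simulate_curves()`, `make_phantom()`);
* a benchmark harness comparing all estimators in log-flow space
  (`run_benchmark()`, `logspace_r2()`).

Fit results are tibbles (broom-style `tidy()`/`glance()`), with
`autoplot()` methods for maps and curves, and TIFF+JSON serialization for
interchange. A thin command-line front end lives in `inst/cli/remi.R`.

## Worked example

```r
library(remispeckle)

# 20 log-spaced exposures, 20 us - 650 ms
ladder <- exposure_set("logspaced", n = 20, t_min = 2e-5, t_max = 0.65)

# synthetic vessel-model curves with known ground truth
sim <- simulate_curves(
  simulation_grid(inv_tau_c = 10^seq(2, 4, length.out = 5),
                  rho = c(0.7, 0.9), d_mu = 0),
  ladder)

fit <- remi_pipeline(sim$stack)
dplyr::select(tidy(fit), row, col, beta, rho, tau_c, d_mu)
#> # A tibble: 10 x 6
#>      row   col  beta   rho    tau_c   d_mu
#>    <int> <int> <dbl> <dbl>    <dbl>  <dbl>
#>  1     1     1  1.00 0.709 0.0106   0.106
#>  2     2     1  1.00 0.703 0.00331  0.0995
#>  3     3     1  1.00 0.701 0.00104  0.101
#>  4     4     1  1.01 0.702 0.000326 0.111
#>  5     5     1  1.02 0.703 0.000101 0.118
#>  6     1     2  1.00 0.927 0.0112   0.130
#>  7     2     2  1.00 0.908 0.00341  0.119
#>  8     3     2  1.00 0.903 0.00106  0.118
#>  9     4     2  1.01 0.901 0.000332 0.127
#> 10     5     2  1.02 0.901 0.000103 0.131

logspace_r2(sim$truth$inv_tau_c, 1 / tidy(fit)$tau_c)
#> [1] 0.9999152
```

Each row is one pixel: the estimator recovers the normalization (`beta`
within ~2%), the dynamic-scattering fraction (`rho` within ~0.03) and the
correlation time (`tau_c`, seconds; here within ~6% of the simulated
`1/inv_tau_c`) without any iterative fitting; `d_mu` near 0 identifies the
ordered-scattering (vessel) model. The final line is the squared Pearson
correlation between true and estimated `log10(1/τ_c)` — the benchmark
metric used throughout.

The same pipeline applied to measured data:

```r
stack <- read_contrast_stack("stack.tif")      # TIFF + JSON sidecar
fit   <- remi_pipeline(stack, spatial = TRUE)  # sREMI variant
write_fit_maps(fit, "maps/")
autoplot(fit)
```

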