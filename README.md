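# coastpulse

Quantitative tools for detecting mid-Holocene coastal marine production
pulses and the human response to them, built for palaeoecologists and
archaeometricians working with radiocarbon date archives, sediment-core
proxies, diatom transfer functions and collagen stable isotopes.

The package grew out of the Southern Scandinavian problem: shell middens
dominated by the European flat oyster (*Ostrea edulis*) appear along Danish
coasts around 7600 cal BP and peak before the introduction of agriculture at
ca. 5900 cal BP, coinciding with two episodes of elevated coastal marine
production (P1, 7600–7100 cal BP; P2, 6400–5900 cal BP). Testing that
coincidence quantitatively takes four statistical machines, which this
package provides as composable, tidyverse-style functions, each paired with
a synthetic-data generator that carries known ground truth so every stage is
testable offline.

## What it computes

**Radiocarbon calibration and SPD null tests.** A determination
r ± σ_lab is calibrated against a tabulated curve (μ(θ), σ_c(θ)) on a 1-yr
calendar grid; the posterior mass at age θ is proportional to

    exp( −(r − ΔR − μ(θ))² / 2(σ_lab² + σ_ΔR² + σ_c(θ)²) )

normalized to 1 (`calibrate()`). A date archive's summed probability
distribution (SPD, `sum_spd()`) is compared against a Monte-Carlo null in
which the same number of dates is deposited uniformly over a calendar
window, back-calibrated (`uncalibrate()`) with lab errors resampled from the
observed pool, and re-calibrated (`simulate_null()`); maximal runs of the
observed SPD outside the null's percentile band are reported by
`spd_deviations()`.

**WA-PLS transfer functions.** `wapls()` fits weighted-averaging partial
least squares: component scores are iterated abundance-weighted averages of
the residual environmental target, orthogonalized with sample weights
proportional to assemblage totals, and regressed against the environment
(inverse deshrinking). `wapls_boot()` bootstrap-validates (out-of-bag RMSEP,
with the s1/s2 decomposition); `reconstruct_salinity()` back-transforms
square-root-unit predictions and expresses them as deviations from modern
salinity. `tidy()`, `glance()` and `autoplot()` methods summarize fits.

**Age-depth models and proxy flux.** `age_depth_model()` builds a
reversal-checked piecewise-linear age-depth interpolant; `compute_flux()`
converts proxy concentrations to accumulation rates (concentration × SAR);
`composite_zscores()` pools per-site standardized flux series and smooths
them with a lowess (span 0.1, tricube weights, 3 robustifying iterations);
`detect_production_phases()` delimits phases where the smoothed composite
exceeds a z-score threshold.

**Isotope diet partitioning.** `summarize_by_period()` groups human/dog
collagen δ¹³C, δ¹⁵N and δ²H by cultural period (Kongemose 8400–7400,
Ertebølle 7400–5900, earlier/later Neolithic 5900–5000/5000–4000 cal BP)
into box-plot summaries; `mixing_fraction()` converts a δ value into a
marine-resource fraction with a two-endmember linear mixing model
f = (δ − δ_terrestrial)/(δ_marine − δ_terrestrial).

## Worked example

A full synthetic study at archive scale — 231 dates with pulses injected at
3:1 odds, a 200-simulation uniform null over 8100–3500 cal BP:

```r
library(coastpulse)

curve <- make_calcurve(span = c(12000, 0), sigma = 15, seed = 1)
dates <- sample_dates(
  intensity = tibble::tibble(old   = c(8000, 7600, 6400),
                             young = c(4000, 7100, 5900),
                             rate  = c(1, 2, 2)),
  n = 231, error_pool = seq(40, 80, by = 5), curve = curve, seed = 2)

spd <- sum_spd(dates, curve, grid_range = c(8100, 3500))
env <- simulate_null(231, dates$c14_error, c(8100, 3500), curve,
                     n_sims = 200, seed = 3)
spd_deviations(spd, env)
#>   cal_bp_old cal_bp_young sign duration  edge
#> 3       7584         7086    +      498 FALSE
#> 4       6319         5967    +      352 FALSE
#> ...
```

The two (+) runs recover the injected pulse windows (7600–7100 and
6400–5900 cal BP); the remaining rows are (−) runs where the archive is
thinner than the uniform null, including edge-flagged runs where the null is
biased by calibration spill-over. The same pulses injected into three
synthetic sediment cores are recovered by the flux composite:

```r
fluxes <- lapply(1:3, function(i) {
  sim <- make_core(site = paste0("site_", i), seed = 10 + i)
  compute_flux(sim$core, age_depth_model(sim$control), "pigment_flux_proxy")
})
detect_production_phases(composite_zscores(fluxes))
#>   cal_bp_old cal_bp_young duration peak_z
#> 1       7560         7170      390   1.18
#> 2       6370         5940      430   1.24
```

A WA-PLS salinity model on the standard synthetic Gaussian-niche training
set (150 samples × 40 taxa along a 0–30 salinity gradient, square-root
transformed environment):

```r
ts <- make_training_set(seed = 4)
fit <- wapls(ts$abundances, ts$env, n_components = 2, transform = "sqrt")
wapls_boot(fit, n_boot = 200, seed = 5)
#>   component rmsep_boot r2_boot     s1    s2
#> 1         1      0.269   0.954 0.0447 0.269
#> 2         2      0.144   0.987 0.0333 0.142
```

Adding the second component cuts the bootstrap RMSEP roughly in half —
the behaviour that motivates two-component models for diatom-inferred
salinity. Finally, the synthetic collagen isotope compilation summarized by
period, and the canonical Mesolithic δ¹³C signature of −13 ‰ expressed as a
marine fraction:

```r
summarize_by_period(make_isotope_compilation(seed = 6)) |>
  dplyr::filter(isotope == "d13c")
#>              period taxon isotope  n  mean median    q1    q3   min   max
#> 1         Kongemose human    d13c 14 -12.9  -12.9 -13.5 -12.4 -14.0 -11.6
#> 2         Ertebolle human    d13c 12 -13.2  -13.3 -13.7 -12.6 -14.3 -11.7
#> 3 earlier Neolithic human    d13c 42 -20.1  -20.2 -20.6 -19.6 -21.6 -17.9
#> 4   later Neolithic human    d13c 18 -20.3  -20.2 -21.1 -19.6 -21.4 -19.2

mixing_fraction(-13, mixing_config(), "d13c")$fraction
#> [1] 0.8888889
```

The whole analysis can also be driven from one configuration:
`run_pipeline(run_config(simulate = TRUE, seed = 1))` executes every stage,
writes tidy CSVs with provenance headers and a JSON run report, and is
byte-reproducible from its seed.

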