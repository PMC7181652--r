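---
title: "Methods: detecting coastal production pulses from dates, cores and collagen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting coastal production pulses from dates, cores and collagen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coastpulse)
```

This vignette is the package's own account of its statistical machinery:
the models, their assumptions, the parameters that matter, the numerical
conventions, and what the synthetic-data tests do and do not establish about
real data.

## 1. Radiocarbon calibration

A calibration curve is a tabulated map θ → (μ(θ), σ_c(θ)) from calendar age
(cal BP, present = AD 1950) to conventional ¹⁴C age with its own 1σ error.
Between knots both μ and σ_c are interpolated linearly — standard practice,
and adequate because both surfaces are smooth at the 5–20 yr knot spacings
in use. For a determination r ± σ_lab with an optional marine reservoir
offset ΔR ± σ_ΔR, the unnormalized calibrated density on the calendar grid
is

$$p(\theta) \propto \exp\!\left(-\frac{(r - \Delta R - \mu(\theta))^2}
{2(\sigma_{lab}^2 + \sigma_{\Delta R}^2 + \sigma_c(\theta)^2)}\right).$$

Conventions, each pinned deliberately:

* **Grid**: integer calendar years, ascending (young → old), probability
  *mass* per 1-yr cell. Mass (not density) makes SPD summation exact
  addition, and `grid_step` is exposed for convergence checks — halving it
  moves 95.4% HPD bounds by at most 2 yr on wiggly synthetic curves.
* **Normalization without the 1/σ(θ) prefactor**: the likelihood above is
  used as written, then normalized to total mass 1. With constant curve
  error the prefactor cancels anyway; where σ_c varies the convention
  matters in the fourth decimal and is pinned so the fine-grid oracle in
  the tests is exact.
* **Trimming**: the grid is cut to the *smallest contiguous* span holding
  ≥ 1 − 10⁻⁵ of the mass, then renormalized. This bounds memory without
  perturbing any downstream sum beyond 10⁻⁵ before renormalization.
* **Degenerate input**: if the likelihood underflows everywhere (max
  unnormalized density < 10⁻³⁰⁰), calibration fails loudly rather than
  returning a normalized artefact of floating-point noise.
* **Curve agnosticism**: the engine takes any curve file with (cal BP, ¹⁴C
  age, error) columns. Marine calibration is expressed as `kind = "marine"`
  plus a per-date ΔR ± σ_ΔR subtracted from the determination, defaulting
  to zero; this supports both common reservoir conventions without
  hard-coding constants the source records do not state.

Back-calibration (`uncalibrate()`) is the exact inverse operation needed for
simulation: μ(θ) plus Gaussian noise with sd √(σ_c² + σ_lab²). Its
closed-form spread is verified against 10⁴ Monte-Carlo draws in the tests.

## 2. The SPD and its uniform-calendar null

The summed probability distribution of a date archive is the elementwise
sum of unit-mass calibrated densities — a proxy for dated-event frequency.
Its sampling behaviour under calibration is notoriously wiggly, so peaks
are judged against a Monte-Carlo null: each simulated archive draws the
same number of calendar ages uniformly over a window deliberately wider
(8100–3500 cal BP by default) than the analysis window (8000–4000), assigns
each age a lab error resampled with replacement from the observed errors,
back-calibrates, re-calibrates and sums. Resampling observed errors is the
simplest faithful reading of "an error distribution similar to the real
data"; a parametric alternative would add assumptions without adding power.

The envelope records the pointwise mean and a central percentile band
(default 95%). The mean alone cannot make "peaks" operational, hence the
band; its coverage is configurable and widening it can only widen the
envelope (tested). Deviations are maximal runs outside the band, discarded
below a 50-yr duration floor (shorter runs are calibration texture, not
demography), and flagged when they touch the outer 100 yr of the window,
where uniform-null mass leaks outward and the band is biased low. No
site/phase binning is applied: the archive is treated as a plain collection
of dates.

For throughput the null calibrates all dates of a simulation in one matrix
operation; the tests assert this path equals a per-date `calibrate()` loop
to 10⁻¹². Scales used here: the analytic-level check runs 200 simulations
of 231 dates (seconds to tens of seconds); the pulse-recovery study runs
20 replicate analyses at 200 simulations each (a few minutes). These sizes
were chosen as the smallest at which the Monte-Carlo standard errors are
comfortably below the effects being measured.

## 3. WA-PLS transfer functions

Weighted-averaging partial least squares predicts an environmental variable
x (here salinity, optionally √-transformed) from taxon abundances Y. With
W = Y/ΣY, sample weights r_i = Σ_k W_ik and taxon weights c_k = Σ_i W_ik,
each component a is built as:

1. taxon scores u_k = Σ_i W_ik e_i / c_k, where e is the current residual
   target (initially the centred environment);
2. sample scores t_i = Σ_k W_ik u_k / r_i;
3. orthogonalization of t against earlier components and standardization,
   both under the weights r;
4. weighted least-squares regression of x on the components (the inverse
   deshrinking step), whose residuals become the next target.

The orthogonalization/standardization chain is *folded back* into
taxon-level coefficients, so a stored model predicts from relative
abundances alone, and in-sample prediction reproduces the apparent fitted
values to machine precision (tested). Component 1 is then exactly classical
weighted averaging with weighted inverse deshrinking, which the tests verify
against an independently coded WA oracle at 10⁻⁸.

Conventions:

* **Weights ∝ row totals.** Percentage data make the weights equal; count
  data give noisier assemblages less influence. A global rescaling of the
  abundance matrix changes nothing (tested): WA-PLS sees composition only.
* **Apparent RMSE is weighted** by the same r used in fitting, which
  guarantees it is non-increasing in component count; apparent r² is the
  plain squared correlation, the figure usually quoted for transfer-function
  models.
* **Bootstrap validation** resamples samples with replacement, refits, and
  predicts the out-of-bag samples. RMSEP per component is the pooled
  out-of-bag root mean square error; the s1 (within-sample bootstrap
  spread) / s2 (bias of averaged predictions) decomposition is reported
  alongside because both conventions circulate in the palaeo literature. A
  cycle whose bootstrap sample holds fewer than two distinct environmental
  values is redrawn (at most 10 times); taxa absent from a bootstrap sample
  are dropped for that cycle, and an out-of-bag assemblage composed
  entirely of such taxa is skipped for that cycle.
* **√ units.** When the environment is fitted as √salinity, predictions are
  back-transformed by squaring (which cannot produce negative salinity) and
  the bootstrap RMSEP is propagated by the delta method,
  se ≈ 2·|estimate_√|·se_√. The RMSEP is attached to every fossil sample as
  its standard error; it is a *common* model error, so averaging fossils
  does not shrink it — the parameter-recovery test respects this.
* **Modern reference.** Reconstructions are reported as deviations from a
  user-supplied modern salinity; the package does not guess per-site
  constants.

## 4. Age-depth models, flux and the composite

Age-depth models are piecewise-linear through dated control points (in
practice medians of calibrated densities), with strict monotonicity in both
depth and age enforced at construction — any reversal is reported with the
offending pairs rather than silently smoothed. Piecewise-linear is the
simplest model whose derivative (the sediment accumulation rate, cm/yr) is
well-defined everywhere; at an interior knot the younger segment's slope
applies. Extrapolation beyond the dated span is refused. Bayesian
alternatives (Bacon-style) are out of scope; for flux work on
multi-century pulses the linear model's bias is second-order.

Proxy flux is concentration × SAR, in the proxy's native concentration unit
per cm² per yr; no dry-bulk-density correction is applied (the concentration
basis follows each proxy's native unit). Flux is linear in both factors
(tested).

The multi-site composite restricts each site's flux series to the analysis
window (8000–4000 cal BP by default), standardizes it per site to mean 0
and sd 1 *within that window* — so sites with different absolute
productivity contribute equally — pools all points, and smooths with
`stats::lowess`: tricube weights, local linear fits, 3 robustifying
iterations, `span` as the fraction of pooled points (0.1 by default),
evaluated on a 10-yr grid. The robust iterations matter: they damp single
outlying samples but also attenuate genuine boxcar pulses somewhat, which
is why phase detection operates on a threshold well below the pulse
amplitude. Production phases are maximal grid runs where the smooth exceeds
0.5 z-score units for at least 100 yr. That threshold pair is an
operational convention of this package — recorded in the output attributes,
not a published constant — chosen so that 3× boxcar pulses at realistic
noise are delimited with midpoints within a few decades of truth while flat
composites yield nothing.

## 5. Isotope summaries and two-endmember mixing

Samples are grouped by cultural period, either from an explicit label or
from a calendar age via the period table (Kongemose 8400–7400, Ertebølle
7400–5900, earlier Neolithic 5900–5000, later Neolithic 5000–4000 cal BP).
The boundary rule is old ≥ age > young, so an age exactly on a boundary
belongs to the younger period (5900 cal BP is earlier Neolithic); the
youngest bound is additionally closed so the table span is fully covered.
Box summaries are n, mean, median, quartiles, minimum and maximum per
isotope; quartiles use linear-interpolation quantiles (R type 7, the
"inclusive" convention) — pinned because exact tests require a pinned
definition. Humans and dogs are summarized separately by default; pooling
is a flag.

The mixing model is linear with two endmembers per isotope:
f = (δ − δ_T)/(δ_M − δ_T), clipped to [0, 1] with clipping flagged (real
collagen values can overshoot endmembers through trophic enrichment or
endmember misspecification). The default endmembers — δ¹³C −12/−21 ‰,
δ²H +70/−10 ‰ — are package conventions for exploration and simulation,
*not* published constants; δ¹⁵N is excluded from mixing by default because
it is trophic-level enriched, not a conservative source tracer. Serious
diet reconstruction should use study-specific endmembers (and ideally a
Bayesian mixing model, which is out of scope here).

## 6. The synthetic generators: what they emulate, what they do not

Every generator is a pure function of its parameters and a seed, returns
its latent truth alongside the data, and regenerates bit-identically.

* `make_calcurve()`: monotone wiggly curves μ(θ) = θ + A·sin(2πθ/P) +
  smooth spline noise, constant σ_c. Parameter combinations violating
  monotonicity (2πA/P ≥ 1) are refused. Emulates curve wiggles at the
  amplitude scale of real atmospheric curves; does not emulate plateaux or
  reservoir-age structure.
* `sample_dates()`: calendar ages from a piecewise-constant occupation
  intensity (boxcar pulses over a background; the standard study injects
  7600–7100 and 6400–5900 cal BP at 3:1 odds), lab errors resampled from a
  pool spanning 40–80 ¹⁴C yr, the empirical scale of shell-date archives.
  Does not emulate taphonomic loss or site-level clustering.
* `make_training_set()`: Gaussian (unimodal) niches on a 0–30 salinity
  gradient — 150 samples, 40 taxa, peak abundance 100, tolerances 2–5
  salinity units, Poisson counts. The defaults give a training set a real
  diatom ecologist would call well-behaved: apparent r² ≈ 0.95+ at two
  components. Real assemblages add zero-inflation, secondary gradients and
  taxonomic noise that this generator deliberately omits, so passing tests
  demonstrate algorithmic correctness, not field-ready transfer accuracy.
* `make_core()`: constant sedimentation (0.05 cm/yr), boxcar production
  pulses (multiplier 3), multiplicative lognormal concentration noise
  (sdlog 0.3 by default — the scatter scale of real pigment and diatom flux
  records; mean-one so the truth is unbiased), exact control points.
  Does not emulate bioturbation smoothing, hiatuses or step changes in
  sedimentation rate.
* `make_isotope_samples()` / `make_isotope_compilation()`: two-endmember
  mixtures with period-dependent marine fractions and Gaussian noise. The
  compilation is a synthetic stand-in at documented group sizes (14, 12,
  42, 18; δ²H on a 4 + 8 subset) around the canonical period signatures
  (δ¹³C −13/−20 ‰, δ¹⁵N 13/9.5 ‰, δ²H +66/−5 ‰) with spreads of 0.8 ‰
  (0.8 ‰, 8 ‰ for δ²H) chosen to match within-period scatter in published
  collagen compilations. Because the effective marine fraction differs
  between tracers in real data, the generator accepts per-isotope fractions
  per period.

## 7. Problem sizes and the study configurations

The test suite and the acceptance script run, as the package's standard
study sizes: a 500-date calibration battery; 200–500 null simulations for
level and flatness checks; 200 bootstrap cycles on the 150 × 40 training
set; and 20 replicate end-to-end studies (3 cores + one 231-date archive
with 200 null simulations each) for pulse recovery. These sizes put every
Monte-Carlo standard error well below the corresponding effect size; the
pipeline default of 1000 null simulations and 1000 bootstrap cycles matches
the scale a publication-grade analysis would use.

## 8. Known limitations

* The uniform null is the only demographic null implemented; exponential or
  logistic growth nulls, taphonomic corrections and site binning are not.
* Piecewise-linear age-depth models understate age uncertainty; control
  point σ is carried as metadata but not propagated into flux errors.
* RMSEP is attached to reconstructions as a constant per component; fully
  sample-specific bootstrap errors would require retaining per-cycle
  models.
* The mixing model is deterministic two-endmember; no fractionation priors,
  no concentration dependence, no multi-source resolution.
* Phase detection depends on an explicit z-threshold convention; its output
  carries that convention precisely so downstream users can re-detect under
  their own.
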