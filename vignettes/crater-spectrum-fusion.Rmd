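---
title: "Crater–spectrum feature fusion for LIBS calibration: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crater–spectrum feature fusion for LIBS calibration: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(craterspec)
```

## The problem

Laser-induced breakdown spectroscopy quantifies an element from the
intensity of its emission lines: within one homogeneous material, line
intensity is close to proportional to concentration. Commercial botanical
powders, however, differ in texture, particle size and elemental background.
These differences modulate how much material each laser pulse ablates and
how the plasma evolves, which multiplies the whole spectrum of each sample
by an unknown, sample-dependent factor — the matrix effect. The symptom is
characteristic: calibration curves fitted within a single product are
excellent, while a curve pooled over several products degrades sharply.
`craterspec` addresses this for cadmium quantification in the 210–231 nm
window, where the three Cd analytical lines (Cd II 214.44, Cd II 226.50,
Cd I 228.80 nm) live alongside Fe, Al, Si and Ca lines; Cd II 226.50 nm in
particular is overlapped by Fe II 226.48 / Fe I 226.50 nm in plant
matrices.

## Characteristic peak ratio correction (CPRC)

Let `X` be the n × p intensity matrix on a shared wavelength axis, `x_N`
the per-sample intensity of the chosen characteristic peak, and `y` the
reference concentrations (ICP-MS values, µg/g). For every wavelength bin
`j`, form the ratio `B_j = x_N / z_j` (one value per sample, `z_j` the
intensity at bin `j`) and score the bin by the Pearson correlation `r_j`
between `B_j` and `y`. A bin whose intensity tracks the sample's
multiplicative factor — a clean background bin — makes `B_j` proportional
to concentration, hence `r_j` near 1. Bins are ranked by signed `r`
descending; for each prefix of size `m = 1..10` the full spectrum is
corrected as `X' = X / Z̄` with `Z̄` the per-sample mean intensity over the
prefix bins, a PLSR model on the corrected spectrum is 10-fold
cross-validated against `y`, and the prefix with the minimal CV-RMSE is
kept. Applying the model divides any new spectrum (same axis) by its own
`Z̄`, so a per-sample constant multiplier cancels *exactly* — this is the
mechanism, and the package asserts it to 1e-10 in its tests.

Design choices a user should know:

* **Signed `r`, not |r|.** Ranking uses `r` descending; a negatively
  correlated ratio indicates a bin that does not behave like a shared
  background and is deliberately not favored. `|r|` ranking is a
  conceivable alternative but is not used.
* **Full prefix scan.** All prefix sizes 1..10 are evaluated and the global
  minimum of the CV path taken (ties go to the smaller `m`), rather than
  stopping at the first local minimum.
* **The peak cannot correct itself.** Bins inside the peak's own extraction
  window (± `peak_window_nm`) are flagged invalid, as are bins with a zero
  intensity in any sample or with zero ratio variance.
* **Cross-validation.** Folds are shuffled once from a recorded seed and
  shared across prefix sizes, so the path is comparable point to point; the
  inner regressor is PLSR with 5 components (capped at the data rank). The
  PLSR engine is a compact SIMPLS implementation kept inside the package so
  that the selection loop (some hundred fits per fitted correction) stays
  in the millisecond range; it is cross-checked in the test suite against
  an independent PLS implementation and against OLS at full rank.
* **Degenerate inputs.** Constant references, fewer than three samples,
  non-positive divisors `Z̄`, and fold counts exceeding n are hard errors —
  the error for a non-positive divisor names the offending sample.

## Crater-morphology compensation

The crater left by ablation proxies the ablated mass: loosely textured
powders yield larger, deeper craters and stronger signals. Nine morphology
parameters (volume µm³; cross-sectional and surface area µm²; average and
maximum depth µm; perimeter, horizontal/vertical Feret diameters,
circle-equivalent diameter µm) plus the raw intensities of the three Cd
lines enter a backward stepwise multiple linear regression on the reference
concentrations: fit OLS, compute each coefficient's two-sided t-test
p-value (t = b/SE, df = n − k − 1), drop the single variable with the
largest p above `alpha = 0.05`, refit, repeat until all survivors are
significant or one variable remains. Two notes:

* The significance test is the standard coefficient t-test — the only
  construction that yields one p-value per variable per iteration, which is
  what the procedure's bookkeeping (the recorded p-value trajectory)
  requires.
* Features enter in raw units. Coefficient t-tests are scale-invariant, so
  standardization would change nothing about the selection; leaving units
  intact keeps the final coefficients interpretable.
* The p-value trajectory of a variable need not be monotone — a variable
  can be insignificant mid-path and significant at the end once collinear
  competitors have been removed. The procedure is run literally; such
  trajectories are recorded, not corrected.

## Calibration models and evaluation

The model grid spans a univariate calibration curve (concentration
regressed on one intensity), MLR, PLSR (SIMPLS; component count fixed or
chosen by seeded CV), a least-squares SVM, and a random forest
(`randomForest`, 500 trees, mtry = k/3, seeded). The LSSVM is the standard
equality-constrained dual: solve
`[[0, 1ᵀ], [1, K + I/γ]] · [b; α] = [0; y]` and predict
`f(x) = Σ α_i k(x, x_i) + b`. Kernel methods are scale-sensitive, so
features are standardized internally and the transform stored in the model;
hyperparameters default to a seeded 5-fold CV grid with γ ∈ 10^{0..6} and
σ ∈ {0.1, 1, 10} × the median pairwise distance of the standardized
calibration features. The test suite checks the KKT residual of the trained
system (< 1e-8) and the γ → ∞ linear-kernel limit against OLS.

Models report `Rc²`, `RMSEC`, `Rp²`, `RMSEP` (µg/g). For univariate curves
the detection limits use the 3σ convention: the intensity-on-concentration
regression of the calibration data provides the sensitivity slope `A` and
the residual standard deviation σ in intensity space, and
`LOD = 3σ/|A|`, `LOQ = 10σ/|A|` (so LOQ/LOD is exactly 10/3). Whether σ
should live in intensity or concentration space is a convention point on
which practice varies; the intensity-space form is the default because it
is the direct reading of "3σ over slope" when no blank replicates exist,
and `lod_loq(..., sigma_space = "concentration")` exposes the alternative.

The fusion pipeline (`run_grid()`) holds one replicate group out for
prediction and fits *everything* data-dependent — CPRC selection, stepwise
retention, hyperparameter CV — on the calibration groups only. A dedicated
test perturbs the held-out group's reference values and asserts that every
fitted artifact is bit-identical, so leakage would be caught, not assumed
absent.

## What the synthetic generator emulates — and what it does not

No public dataset exists for this design, so the package generates one with
the statistical structure the method assumes (`synthetic_config()`,
`generate_dataset()`):

* **Design:** six brands × ten spike levels (0, 0.5, 1, 10, …, 70 µg/g) ×
  four replicate tablets = 240 samples; replicate k of every (brand, level)
  cell goes to group k, so the standard 3 + 1 group split keeps every
  level of every brand on both sides.
* **Matrix effect:** each brand carries an ablation factor drawn once from
  U[0.5, 1.5]; each sample multiplies it by log-normal shot noise. Line
  emission scales with this factor; the flat continuum scales with
  factor^0.85 (`background_exponent`). The sublinear background is the
  crucial realism choice: with exponent 1 the ratio correction would be
  exact and neither crater fusion nor multi-line models could improve on
  it, which real data contradict. With 0.85, CPRC removes most but not all
  of the matrix effect, and crater parameters — power laws of the same
  factor (volume ~ a³, areas ~ a², depths ~ a, diameters ~ a^0.7, each
  with log-normal measurement noise) — retain independent compensating
  information.
* **Spectral background:** Gaussian lines (σ = 0.05 nm, a proxy for the
  instrumental profile on a 0.02 nm grid; the grid pitch is itself an
  inference, as instrument vendors rarely publish it) on a flat continuum
  of 200 counts, plus a per-sample additive drift ramp that decays to zero
  at 228 nm. The ramp makes the short-wavelength region noisy and leaves
  the 229.5–231 nm tail as the cleanest carrier of the multiplicative
  factor, which is where the fitted corrections gravitate.
* **Interference:** Fe/Al/Si/Ca lines with per-brand log-normal composition
  multipliers; Fe II 226.48 and Fe I 226.50 sit on top of Cd II 226.50, so
  that line's raw calibration is visibly worse than Cd I 228.80 — matching
  the qualitative line ranking a practitioner sees.
* **Ground truth:** true concentration = spike level + a per-brand native
  Cd offset in [0.4, 1.6] µg/g (even unspiked tablets emit Cd); reference
  values carry 1% multiplicative error, emulating ICP-MS repeatability.

The generator does **not** simulate plasma physics: no Saha–Boltzmann
populations, self-absorption, line-shape changes, or temporal gating
effects. Noise is multiplicative log-normal by default (an additive switch
exists) because multiplicative uncertainty is what the method under test
claims to cancel. Consequently, green tests show that the implementation
does what the algorithms promise *under the stated statistical structure*;
they cannot certify performance on any particular instrument or matrix.

## Numerical and testing choices

* Wavelength grid: 210.00–231.00 nm at 0.02 nm (p = 1051) as the synthetic
  default; real files may carry any strictly ascending axis, and sample
  alignment is always by explicit `sample_id`, never row order.
* Peak extraction: window maximum with half-width 0.1 nm; ties break toward
  the bin nearest the nominal wavelength, then the lower wavelength; a zero
  window degenerates to the nearest bin.
* AsLS baseline (for the pretreatment comparison): second-difference
  Whittaker penalty, defaults smoothness 1e5, asymmetry 0.01, 20
  reweighting iterations — standard chemometrics values; the sparse system
  is solved with `Matrix`. Total-area normalization rescales to unit area
  (any common target area is equivalent up to a global constant for all
  downstream models).
* Spectra CSVs are written with 17 significant digits so a write/read
  round trip reproduces doubles exactly.
* Benchmark problem sizes in the test suite: 50 generator seeds for the
  improvement-ordering property, 200 simulated feature sets for stepwise
  recovery, 100 random spectra for scale invariance — sizes chosen so each
  property is measured with comfortable margins while the whole suite runs
  in well under test-budget scale on a single CPU.
* One statistical boundary deserves honesty: a signal-free feature survives
  backward elimination exactly when its final t-test p-value falls below
  α = 0.05, an event with probability ≈ α under the null. The expected
  elimination rate is therefore ≈ 95% *by construction*, and the recovery
  test pins the simulation seed so the asserted rate is a deterministic
  quantity slightly above that expectation rather than a coin flip on it.

## Limitations

* CPRC corrects one characteristic peak per fitted model; multi-element
  simultaneous correction is out of scope (each line gets its own model in
  multi-line fusion).
* The LOD/LOQ convention is residual-σ based; against blank-replicate
  conventions the numbers can differ by a constant factor.
* Random-forest models are in-memory only (seeded and reproducible, but not
  serialized to JSON like curve/MLR/PLSR/LSSVM models).
* The CLI reads wide/long CSV spectra only; vendor binary formats and
  resampling between wavelength grids are intentionally unsupported.
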