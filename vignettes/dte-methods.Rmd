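---
title: "Methods: stress accumulation, thrombogenic footprints and activation rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stress accumulation, thrombogenic footprints and activation rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtemu)
```

## The model

Flow-induced platelet activation is driven by the combination of shear
stress and exposure time. `dtemu` post-processes Lagrangian platelet
trajectories — time series of position and stress tensors sampled along a
particle path through a device — into a per-trajectory **stress
accumulation** (SA), and treats the distribution of SA over an ensemble
of trajectories as the device's **thrombogenic footprint**.

Three modelling commitments underlie the core:

1. **Total stress is additive.** The viscous stress tensor and, where a
   turbulence closure provides one, the Reynolds stress tensor are summed
   componentwise *before* any scalar reduction
   (`total_stress()`/`add_scalar_stress()`). Turbulent stresses are never
   folded in as a separate scalar term; doing so would double-count
   orientation effects.

2. **Scalar stress is the √J₂ invariant.** A symmetric total tensor is
   reduced to σ = (1/√3)·√(σ₁₁²+σ₂₂²+σ₃₃²−σ₁₁σ₂₂−σ₂₂σ₃₃−σ₁₁σ₃₃+3(σ₁₂²+σ₁₃²+σ₂₃²)),
   the von-Mises-type magnitude of the deviatoric part. This form is the
   standard choice in the shear-induced platelet activation literature:
   it is invariant under rotation of the coordinate frame (a platelet
   does not know the mesh orientation), insensitive to isotropic pressure
   (pure pressure does not shear a platelet), and reduces to the shear
   magnitude |τ| for a pure shear with a single off-diagonal component.
   The suite verifies all three properties directly, the last two
   analytically and rotation invariance under random orthogonal
   conjugation to 1e-9 relative tolerance.

3. **SA is a linear product-sum.** SA = Σᵢ σᵢ·Δtᵢ, in Pa·s. The
   quadrature convention is the right-rectangle rule: σᵢ is the scalar
   stress at the sample that *ends* interval i and Δtᵢ = tᵢ − tᵢ₋₁. CFD
   solvers report state at the end of each step, so this convention
   consumes solver output without interpolation; it is first-order
   consistent (the suite checks the error on a linear ramp halves when
   the step halves) and makes SA exactly additive across any split of a
   trajectory. A single sample spans no interval, so its SA is 0, with a
   warning rather than an error — ensembles clipped to small regions
   legitimately produce such fragments. Power-law alternatives
   SA_{a,b} = (Σ σᵢ^{a/b}·Δtᵢ)^b used in the blood-damage literature are
   provided by `powerlaw_sa()`; a = b = 1 reproduces linear SA
   bit-for-bit. No stress floor or ceiling is applied before summation.

## The footprint and its harmonization

`build_pdf()` bins per-trajectory SA values into a normalized histogram
density (Σ density·binwidth = 1, enforced to 1e-9 on every construction
path). Default binning is Freedman–Diaconis over the data range; when two
footprints are compared visually or per-bin, pass shared edges computed
from the pooled data so the bins align.

Ensembles from different simulations have different sizes (typically
4,000–5,000 seeded platelets), and a footprint's resolution depends on
the count. `bootstrap_pdf()` harmonizes footprints to a common,
physiologically relevant target count: each of `boot_reps` replicates
(default 1000) resamples `target_n` values with replacement, is binned on
edges frozen from the source sample, and the reported density is the
replicate mean with 2.5/97.5-percentile bands per bin. Resampling to a
factor-10 target (4,000 → 40,000) is the package's reading of
"interpolating between population sizes by bootstrapping": it is
standard, reproducible and preserves the empirical mean (checked against
the Monte-Carlo standard-error bound 3·sd/√(target_n·boot_reps)). A
degenerate all-identical sample yields a single unit-mass bin with
zero-width bands rather than an error.

SA populations are heavy-tailed — close to log-normal, with high excess
kurtosis and a tail of Tukey outliers (`sa_summary()` reports Fisher
excess kurtosis and flags, but never removes, values outside
Q1 − 1.5·IQR / Q3 + 1.5·IQR). Footprint comparison therefore defaults to
the two-sided Mann–Whitney rank test; `method = "log_t"` performs Welch's
t-test on log-transformed values for users who prefer transforming
log-normal data to normal. Per-ROI comparisons report unadjusted p-values
by default, with an optional Bonferroni adjustment
(`compare_roi_footprints(..., adjust = "bonferroni")`).

## Regions of interest

ROIs are cylindrical shells aligned with the device rotation axis,
defined by half-open intervals in z, r and optionally θ. Half-open
intervals make a partition of the device exact: every sample belongs to
exactly one region of a partition, which the suite asserts. Pass-through
fractions count trajectories with at least one *sample* inside the ROI —
membership is not interpolated across boundary crossings, so a very
coarse Δt can miss a brief passage; this is a documented limitation, not
a bug, and matches how trajectory exports are typically post-processed.

## Hot-spot waveforms and the shearing device

`rank_hotspots()` orders trajectories by total SA (default) or peak
scalar stress — both criteria are reasonable definitions of "extreme
loading", so both are exposed — with ties broken deterministically by
trajectory id. `extract_waveform()` linearly interpolates the scalar
stress onto a uniform grid, because a programmable cone-plate device
consumes uniform command steps while CFD sampling is irregular; negative
interpolated values are clipped at zero (scalar stress is nonnegative by
construction; clipping only guards floating-point noise).
`hsd_program()` maps stress to cone speed by the small-angle cone-plate
relation ω = τ·α/μ, validated against the motor's speed limit; the
calibration (viscosity, cone angle, max speed) is explicit configuration
so other devices can be mapped. The mapping is linear and exactly
invertible, which the suite exploits as a round-trip property.

## PAS series and activation rates

PAS values are fractions of the sonicated (fully activated) maximum.
The Platelet Activation Rate is the slope of an ordinary least-squares
fit of PAS on time in minutes, with a **free intercept**: baseline
activation exists in real assays, and forcing the line through the t = 0
measurement would bias the slope. Device comparison uses one-way ANOVA on
**per-donor slopes**: the donor is the experimental unit (10 donors for
platelet-only experiments, 5 with red cells), and pooling measurements
would overstate the effective sample size. An ANCOVA-style
time-by-condition interaction test (`method = "interaction"`) is provided
as the more powerful measurement-level alternative; the per-donor ANOVA
remains the default. Donors with fewer than two distinct timepoints
cannot contribute a slope and are excluded with a warning. `par_ratio()`
reports the slope ratio between designs with a delta-method standard
error.

## What the synthetic generators emulate

The generators encode only what is published about the two VAD designs at
the clinical operating point (9,500 rpm, 4 L/min):

* overall footprint statistics — mean SA 16.2 ± 14.4 Pa·s (original
  design) and 3.5 ± 3.3 Pa·s (optimized) — as log-normal populations
  whose parameters are **moment-matched** (`lognormal_match()`:
  sdlog² = ln(1 + s²/m²), meanlog = ln m − sdlog²/2), so the analytic
  mean and sd equal the targets exactly and sample moments converge at
  the Monte-Carlo rate;
* hot-spot peak-stress ranges — 200–600 Pa (original) versus below
  200 Pa (optimized). Only the upper design's range is printed as an
  interval; for the optimized design the generator draws peaks in
  [100, 200) Pa, the upper half of the sub-threshold band, as a
  representative choice;
* activation rates — PAR 3×10⁻⁴ min⁻¹ (original) and 3×10⁻⁵ min⁻¹
  (optimized) at the assay schedule t = 0, 10, 20, 30 min.

Everything else is explicit configuration with defaults chosen once as
realistic for this kind of assay and stated here: synthetic PAS series
use a baseline activation of 0.01 and Gaussian measurement noise with
sd 2×10⁻⁴ — about 20 % of the optimized device's activation rise over a
30-minute loop run, the regime in which the slope comparison is
informative rather than trivial; hot-spot trajectories last 0.05 s at
Δt = 10⁻⁴ s with a 10 Pa baseline and one to three brief Gaussian peaks
rescaled so the maximum lands in the preset range; `preset_ensemble()`
draws residence times uniformly on 0.02–0.1 s and encodes each
trajectory's SA as a constant pure-shear stress, with seeds uniform on a
disk normal to the axis, mirroring injection from a plane upstream of the
inlet.

Analytic fields (uniform, plane Couette, solid-body rotation, annular
gap) provide trajectories whose stress is known in closed form: plane
Couette at U = 1 m/s, h = 1 mm, μ = 0.0035 Pa·s gives every trajectory a
constant scalar stress μU/h = 3.5 Pa and SA = 3.5 Pa·s over one second,
exactly. Advection uses classical fixed-step RK4; on solid-body rotation
the radius drift shrinks by at least the fourth-order factor of 16 per
step halving (the amplitude error of RK4 on circular orbits in fact
decays by about 32× per halving, and the test brackets accordingly).

**What the synthetic data does not emulate.** Real CFD trajectories have
spatially correlated, tensorially full stress histories, recirculation
and residence-time distributions set by the device geometry; the
generators produce none of that structure. Passing tests therefore
demonstrate that the *computational machinery* — invariants, quadrature,
bootstrap, statistics, file handling — is correct under populations with
the published summary statistics, not that any particular device has
those statistics. Region-specific footprints of the real devices (and
the published 94 %/84 % shroud-gap pass-through fractions) depend on the
proprietary geometries and full-scale simulations and are out of reach at
desk scale; `clip_to_roi()`/`roi_pass_fraction()` are instead validated
against brute-force membership oracles on constructed ensembles.

## Numerical choices and degenerate inputs

* Tensor symmetry is enforced to 1e-9 relative to the largest entry;
  violations name the offending components.
* The invariant's radicand is clamped at zero before the square root to
  absorb cancellation at machine precision.
* Ensemble CSVs carry a two-line versioned header declaring SI units;
  reading uses base R's correctly rounded double parser so
  write→read→write is byte-stable, and files round-trip to better than
  1e-12 relative.
* Hot-spot ranking ties break by ascending trajectory id; bootstrap and
  all generators take an explicit seed and run in an isolated RNG stream
  (`withr::with_seed`), leaving the caller's RNG state untouched.
* Empty clip results are allowed (a trajectory may simply miss an ROI);
  empty *ensembles* are errors.

## Problem sizes

The test suite runs at deliberately modest sizes — ensembles of a few
hundred to a few thousand trajectories, bootstrap replicates in the
hundreds, 1,000-repetition type-I-error calibrations at α = 0.05 for both
the rank test and the PAR ANOVA — chosen so the whole suite completes in
about a minute on a single core while keeping every Monte-Carlo bound at
3σ or wider. The acceptance script draws the full harmonized population
sizes (40,000 and 50,000) directly.

## Known limitations

* SA quadrature is first-order; heavily under-sampled trajectories bias
  SA (the right-rectangle rule overweights rising stress). Resample the
  source export rather than relying on the quadrature to compensate.
* Pass-through counting by sample membership undercounts brief passages
  at coarse Δt.
* The bootstrap harmonization treats the source ensemble as exchangeable;
  it cannot manufacture tail information beyond the observed maximum.
* The HSD mapping ignores motor acceleration limits and fluid inertia in
  the cone-plate gap; schedules are kinematic set-points, not a hardware
  controller.
* PAS clipping to [0, 1] makes extreme-noise series slightly nonlinear
  near the bounds; at the default noise level the effect is negligible.
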