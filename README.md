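# dtemu — Device Thrombogenicity Emulation toolkit

Rotary blood pumps (ventricular assist devices, VADs) activate platelets
mechanically: shear stress acting over exposure time drives platelets past
their activation threshold, so thrombogenicity is a property of the flow
field, not just the blood-contacting surface. `dtemu` implements the
computational side of Device Thrombogenicity Emulation (DTE) for engineers
and researchers who post-process Lagrangian platelet trajectories from CFD
and correlate them with platelet-activation assays:

* **Stress accumulation.** Along each platelet trajectory the total stress
  tensor (viscous plus turbulent/Reynolds parts, σ = σ_visc + σ_Re) is
  reduced to a rotation-invariant scalar
  σ = √J₂ = (1/√3)·√(σ₁₁² + σ₂₂² + σ₃₃² − σ₁₁σ₂₂ − σ₂₂σ₃₃ − σ₁₁σ₃₃ +
  3(σ₁₂² + σ₁₃² + σ₂₃²)), and the linear stress accumulation
  SA = Σᵢ σᵢ·Δtᵢ (Pa·s) is the product-sum of instantaneous scalar stress
  and exposure time. Power-law variants SA_{a,b} = (Σ σᵢ^{a/b} Δtᵢ)^b are
  available for comparison with blood-damage models.
* **Thrombogenic footprint.** The per-trajectory SA values of an ensemble
  (thousands of seeded platelets) are collapsed into a probability density
  function — the device's "thrombogenic footprint" — and harmonized across
  unequal ensemble sizes by bootstrap resampling to a common target count,
  with per-bin confidence bands. Footprints are compared with
  Mann–Whitney or log-scale Welch tests, overall or per cylindrical
  region of interest (ROI).
* **Hot-spot waveforms.** Extreme stress-loading trajectories are ranked,
  resampled to uniform-grid stress waveforms, and translated into speed
  schedules for a cone-plate Hemodynamic Shearing Device (HSD) via the
  small-angle relation τ = μω/α, so device-specific loading histories can
  be replayed on real platelets in vitro.
* **Platelet activation rates.** Platelet Activity State (PAS) assay
  series (normalized to the sonicated maximum) are fitted as PAS ~ time;
  the slope is the Platelet Activation Rate (PAR, min⁻¹), compared across
  devices by one-way ANOVA on per-donor slopes.
* **Synthetic data.** Analytic flow fields (uniform, plane Couette,
  solid-body rotation, annular gap) with exact stress tensors and RK4
  particle advection, plus seeded generators whose log-normal SA
  populations are moment-matched to published footprints of an original
  and an optimized VAD design — so the full pipeline runs and is testable
  with no proprietary CFD input.

Everything is data-frame first: trajectory ensembles, SA tables, PAS
series, waveforms and schedules are tibbles, and results have
`tidy()`/`glance()`/`autoplot()` methods.

## Worked example

```r
library(dtemu)

# SA populations for the two device presets at realistic seeding counts
orig <- preset_sa_population(device_preset("original"),  n = 4000, seed = 7)
opt  <- preset_sa_population(device_preset("optimized"), n = 5000, seed = 8)

# bootstrap the original footprint up to 40,000 platelets
bootstrap_pdf(orig, target_n = 40000, boot_reps = 1000, seed = 9)
#> <footprint_pdf> 109 bins on [0.830642, 174.565] Pa.s; n_source 4000; bootstrapped to n = 40000 (1000 reps)
#>   mean 16.3  sd 14.4  skew 2.93  ex.kurtosis 14.6  max 175  outliers 270

compare_footprints(opt, orig)
#> # A tibble: 1 × 5
#>   method statistic p_value mean_shift direction
#> 1 rank     1599113       0      -12.7 A_lower

fit_orig <- fit_par(synth_pas(device_preset("original"), seed = 10))
fit_orig
#> <par_fit> PAR = 0.000299 min^-1 (se 2.5e-06), intercept 0.00994; 40 points, 10 donor(s)

par_ratio(fit_orig, fit_par(synth_pas(device_preset("optimized"), seed = 11)))
#> # A tibble: 1 × 2
#>   ratio    se
#> 1  10.5 0.820
```

The footprint mean of 16.3 Pa·s (vs 3.5 Pa·s for the optimized preset)
reproduces the moment-matched calibration targets; the comparison shows a
highly significant shift of the optimized design toward lower stress
accumulation (`A_lower`, p ≪ 0.01); and the fitted activation-rate ratio
of ~10 reflects the order-of-magnitude thrombogenicity reduction the
presets encode. `rotor_step_angle(9500, 7e-5)` returns 3.99 — a 7.0×10⁻⁵ s
solver step at the 9,500 rpm operating point sweeps a 4° rotor angle.

A command-line front end over the same functions is installed at
`system.file("cli", "dte.R", package = "dtemu")`, with subcommands `sa`,
`footprint`, `compare`, `hotspots`, `hsd-export`, `par`,
`synth-ensemble` and `synth-pas`.

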