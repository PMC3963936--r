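# stunmird

Internal radiation dosimetry and thyroid-stunning analysis for
⁹⁹ᵐTc-pertechnetate in the mouse, as an R package.  It is aimed at
preclinical nuclear-medicine groups who need a desk-scale, fully seeded
reimplementation of the classic small-animal dosimetry chain — from decay
data to absorbed dose to downstream radiobiology statistics — that runs and
is testable without any imaging data.

## What it computes

The package follows the MIRD formalism, which separates biokinetics from
radiation physics:

* **Self S-value** `S` (Gy·Bq⁻¹·s⁻¹): absorbed dose to the thyroid per
  decay occurring in it.  Computed by seeded Monte Carlo on a synthetic
  voxel phantom (cubic voxels, default 200 µm; thyroid a voxelized 5.4 mg
  soft-tissue sphere).  Electrons (conversion + Auger, ~16 keV/decay for
  ⁹⁹ᵐTc) are transported on straight continuous-slowing-down tracks using a
  packaged soft-tissue CSDA range table; photons use the analytic
  mean-chord model `1 − exp(−μ_en·ℓ̄)`, `ℓ̄ = 4V/S`.
* **Cumulated activity** `Ã = ½·A_peak·t_peak + (A_peak/λ_eff)(1 −
  e^{−λ_eff(t_end − t_peak)})` (Bq·s): closed-form integral of a per-animal
  time–activity fit — linear uptake from zero to a 1 h peak, then
  mono-exponential washout fitted on log-activity; endpoint 24 h;
  activities not decay-corrected.
* **Absorbed dose** `D = Ã × S` (Gy), plus the peak-activity→dose OLS
  calibration across animals.
* **Stunning statistics**: percent change in rechallenge uptake, a
  dose-threshold scan (midpoint candidates, Student's t-test per split,
  maximally selected split), longitudinal recovery profiles normalized to
  day 0, and comparative-Ct expression `2^−ΔCt`.
* **Synthetic cohorts**: seeded generators reproducing the study's group
  structure (%ID 2.84±0.63 / 2.60±0.35 / 2.67±0.33 / 2.63±0.47 at
  10/25/100/150 MBq, n = 4/9/9/29; a 22 Gy stunning threshold with mean
  changes −3.95% below and −17.5% above; recovery to baseline by day 4).

## Worked example

```r
library(stunmird)

# Radiation physics: S-value on the default 5.4 mg phantom
ph <- build_phantom()
sv <- self_svalue(ph, tc99m_spectrum(), n = 1e6, seed = 1)
sv
#> <svalue_result> S = 4.5405e-10 Gy/Bq/s  (mass 5.443 mg)
#>   relative SE 0.016%  |  1000000 histories/line  |  electron fraction 0.957  |  seed 1

# Biokinetics + dose on a synthetic cohort with the study's group sizes
tac <- synth_cohort(cohort_config(seed = 42))
rep <- run_pipeline(pipeline_config(seed = 42), tac)
rep$dose_by_group
#>   injected_MBq  n mean_dose_Gy sd_dose_Gy
#> 1           10  4     2.334454  0.5095664
#> 2           25  9     4.694335  1.1795840
#> 3          100  9    19.896181  2.6187753
#> 4          150 29    27.661821  5.7211977
rep$calibration$r_squared
#> [1] 0.9450118
```

The simulated S-value lands within a fraction of a percent of the
4.55×10⁻¹⁰ Gy·Bq⁻¹·s⁻¹ used as the pipeline default, with Monte Carlo
uncertainty well below 1%; the four dose-group means fall inside the
reported cohort bands (2.6±1.0, 4.8±0.7, 19.6±2.4, 28.4±5.2 Gy), and the
1 h peak activity alone predicts the 24 h dose with R² ≈ 0.95.

Downstream, a stunning threshold scan on a synthetic rechallenge cohort:

```r
doses <- c(runif(15, 5, 22), runif(15, 22, 35))
rec   <- synth_stunning(stunning_config(seed = 7), doses)
threshold_scan(rec)
# threshold near 22 Gy, p < 0.05; below-group mean ~ -4%, above ~ -17.5%
```

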