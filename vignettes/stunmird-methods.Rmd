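---
title: "Methods: Tc-99m thyroid dosimetry and stunning analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Tc-99m thyroid dosimetry and stunning analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stunmird)
```

## Scope and model

`stunmird` implements the complete quantitative chain of a preclinical
thyroid-stunning analysis for ⁹⁹ᵐTc-pertechnetate in the mouse: radiation
physics (the thyroid self S-value), biokinetics (time–activity fitting and
cumulated activity), the MIRD dose product, and the downstream statistics
(dose-threshold detection, recovery profiling, comparative-Ct expression).
Every stage is exercised on seeded synthetic cohorts, so the package needs
no imaging or animal data to run or test.

The MIRD formalism factorizes the absorbed dose as `D = Ã × S`, where the
cumulated activity `Ã` (Bq·s) counts the decays occurring in the thyroid
over the integration window and the self S-value `S` (Gy·Bq⁻¹·s⁻¹)
converts decays into absorbed dose via the radiation physics of the organ.

## Decay data

The packaged ⁹⁹ᵐTc table (`inst/extdata/tc99m_emissions.csv`) carries the
principal discrete lines of the standard MIRD/ICRP-107 decay compilations:
the 140.511 keV gamma (yield 0.885), its K/L/M conversion electrons
(119.5–140.4 keV), the highly converted 2.17 keV transition, technetium
K/L X-rays, and the Auger groups represented by mean-energy discrete lines.
Totals are 15.85 keV/decay in electrons and 125.8 keV/decay in photons;
discrete lines carry over 99% of the emitted energy, which is why the
continuous Auger spectra are not resolved further.  The physical half-life
(6.0067 h) is carried in the table header and used for all decay
arithmetic.

## Transport model

The S-value Monte Carlo deliberately avoids full coupled photon–electron
transport; in a ~1 mm-radius organ the self dose is dominated by short-range
electrons, and two simple models suffice:

* **Electrons** — straight continuous-slowing-down tracks with constant
  linear energy transfer.  A history samples a decay site uniformly within
  the thyroid voxels and an isotropic direction; the absorbed fraction is
  the fraction of the CSDA range lying inside the thyroid region,
  evaluated at 32 track midpoints against the voxel labels.  Ranges come
  from a packaged soft-tissue (water-equivalent) stopping-power/range
  table, interpolated by a monotone cubic spline in log–log space.
  Electrons below the table's 1 keV floor (range well under a micrometer)
  deposit fully at the decay site with zero variance.  Neglecting track
  curvature and delta-ray escape biases the absorbed fraction upward by at
  most a few percent for the ~120–140 keV conversion electrons whose range
  (~0.2 mm) is still small against the organ; lower-energy lines are
  unaffected (absorbed fraction 1).
* **Photons** — analytic mean-chord attenuation, `φ = 1 − exp(−μ_en·ℓ̄)`
  with `ℓ̄ = 4V/S` of the equal-volume sphere and `μ_en` from a packaged
  mass energy-absorption table.  At 140.5 keV this gives φ ≈ 0.004; the
  photon contribution to the self S-value is under 5%, so the analytic
  approximation is inconsequential.

The phantom is a cubic soft-tissue body (default 20 mm, density
1.05 g/cm³) with a one-voxel air shell, holding a voxelized thyroid sphere
whose radius is tuned so the realized voxel mass matches the target
(default 5.4 mg) within 2%; a voxel too coarse to do so raises a geometry
error.  Decays are sampled uniformly per thyroid voxel, matching a
homogeneous source.

Statistical uncertainty uses batch means: histories are split into 20
equal batches, electron lines share the batches, and the SE is
`sd(batch S)/√20`.  All randomness flows through one explicit seed
(default 20140324) via R's RNG, also inside the compiled transport kernel,
so identical calls are bit-identical.  `n` counts histories per electron
line; at `n = 10⁶` the full-spectrum run takes a few seconds and the
relative SE is ~0.02%, far below the 1% design requirement.

With these choices the default phantom gives S ≈ 4.54×10⁻¹⁰ Gy·Bq⁻¹·s⁻¹
with ~96% of the absorbed energy carried by electrons — consistent with the
4.55×10⁻¹⁰ value the pipeline uses as its fixed default
(`pipeline_config(s_value = ...)`, or `"simulate"` to recompute it).

## Time–activity model

Per animal, the (not decay-corrected) thyroid curve is modeled as a
straight uptake line from the origin to the peak and a mono-exponential
washout.  The peak is by default the first measured sample (`"fixed"`,
matching a 1 h uptake maximum; `"free"` uses the argmax sample).  The
washout rate λ_eff is fitted by least squares on log-activity of the
post-peak samples — exact for the two-point designs used here and
appropriate for multiplicative measurement noise.  λ_eff combines physical
decay and biological clearance; a fit slower than physical decay is
flagged with a warning but not rejected.  The cumulated activity uses the
closed form given in the README, with the 24 h endpoint as default;
decay correction is applied only when reporting %ID, never to Ã.

## Synthetic generators

The generators encode the study conditions as defaults: group %ID
distributions 2.84±0.63 / 2.60±0.35 / 2.67±0.33 / 2.63±0.47 for
10/25/100/150 MBq with n = 4/9/9/29; sampling at 1/3/7 h; a 22 Gy
stunning threshold with mean uptake changes −3.95% (below) and −17.5%
(above), SD 5%; recovery means 55/70/100/100% of baseline at days
1/2/4/8 with 3 animals per day.

Three generator parameters are free choices, not reported values:

* **λ_eff median 0.256 h⁻¹** (log-normal, geometric SD 1.15).  This is
  calibrated analytically: with the mean 150 MBq animal peaking at
  3.945 MBq (2.63 %ID) and S = 4.55×10⁻¹⁰, the closed-form Ã reproduces
  the reported 28.4 Gy group mean exactly at λ_eff = 0.256 h⁻¹
  (effective half-life 2.7 h).  The remaining groups then land at
  2.3/4.7/19.9 Gy, inside their reported bands.  A faster washout of
  0.35 h⁻¹ would push the 150 MBq mean to 21.7 Gy, outside the reported
  28.4±5.2 Gy band, which is why it was not used.
* **Measurement CV 5%**, multiplicative log-normal with unit mean —
  typical of quantitative small-animal SPECT.
* **Day-2 recovery mean 70%** — the study reports impairment "up to two
  days" without a number; 70% encodes partial recovery between the
  measured 55% (day 1) and full recovery (day 4).  Recovery SD 8%.

Negative draws are redrawn (not clipped), keeping distributions unbiased
near zero.  Every generator is a pure function of its config and seed.

What the generators do *not* emulate: image-level effects (partial volume,
salivary-gland spillover, reconstruction bias), diet-dependent uptake, the
correlation structure between %ID and washout within an animal, or any
mechanistic NIS-downregulation kinetics.  Passing tests therefore
demonstrate that the analysis chain recovers the statistical structure it
assumes — not that it would be unbiased on real images.

## Threshold detection

Candidate thresholds are midpoints between consecutive distinct doses with
at least 3 records on each side; each candidate gets a two-sided Student
t-test (Welch behind a flag).  The default selection rule is the
**maximally selected split** (smallest p).  A "smallest significant
candidate" rule is also provided, but it systematically underestimates a
true threshold: when the effect is strong, a split far below the threshold
already separates a pure below-group from a mixed group significantly, so
the first significant candidate is not the change point.  The min-p rule
is the standard change-point practice and localizes correctly.

Two caveats are intentional and documented in the result's `note` field.
First, no multiplicity correction is applied across candidates (the
analysis mirrors a single reported p-value); under a null with many
distinct doses the family-wise false-positive rate of the scan is inflated
(~30% in simulation), while with two dose levels (a single candidate) it
holds the nominal level (~2–5% measured).  Second, exact localization has
an intrinsic ceiling: with mean shift 13.55%, SD 5% and 15 animals per
side, the boundary animal's draw flips the best split by one position with
probability ~0.2 for *any* selection statistic, so the exact-bracketing
rate plateaus near 80% in replicate simulations.

## Recovery classification

Follow-up uptake is normalized per animal to day 0.  A day is classified
`recovered` when its mean is not significantly different from 100% by a
per-day two-sided t-test at α = 0.05 — the same convention used to mark
impaired days in longitudinal figures.  The descriptive rule "mean within
one sample SD of 100%" is reported as the `within_1sd` column but is not
the primary flag: with n = 3 it misclassifies a truly recovered day with
probability P(|t₂| > √3) ≈ 22% regardless of the noise level, which makes
it unsuitable as a classifier at this group size.  One-way ANOVA across
days is reported alongside.

## Numerical choices and degenerate inputs

* Energies in keV, times in hours, activities in MBq; Bq·s appear only in
  Ã, and the keV→J constant is 1.602176634×10⁻¹⁶.
* Emission lines below the configurable yield cutoff (default 10⁻⁶) are
  retained and only flagged, so per-decay energy totals are never
  truncated.
* Degenerate cases are defined, not fatal: zero-volume thyroid gives
  photon φ = 0; one animal per recovery day reports `NA` SD and p; a
  constant recovery day at exactly 100% is recovered with p = 1.
* Problem sizes in the test suite (10⁶ histories at the top end, 200-
  replicate threshold simulations, n = 200 parameter-recovery cohorts)
  keep the full suite under a minute while leaving Monte Carlo SEs an
  order of magnitude below the tolerances they guard.

## Known limitations

The transport model omits track curvature, delta rays, and bremsstrahlung
(sub-percent at these energies); the phantom has no lungs or bone, which
do not affect a *self* S-value; cross-organ doses and human extrapolation
are out of scope.  The TAC model is deliberately minimal — no
compartmental or blood-input modeling — because the 1/3/7 h design cannot
constrain richer models.  The threshold scan reports unadjusted p-values
by design, as discussed above.
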