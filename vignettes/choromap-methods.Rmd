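---
title: "Geographic choroidal-thickness mapping and ocular biometry: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geographic choroidal-thickness mapping and ocular biometry: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

choromap measures two quantities from 1050 nm spectral-domain OCT data of
myopic eyes: the **choroidal thickness (CT)** — the distance from the outer
surface of the retinal pigment epithelium (RPE) to the inner scleral border
(the choroid–sclera interface, CSI), mapped geographically around the
macula — and the **intraocular length (IOL)**, the axial distance from the
anterior cornea to the RPE, measured from a composite A-scan acquired with a
dual-reference-arm geometry. Because no patient scans are distributed with
the package, a synthetic OCT generator with known ground truth stands in for
them: every stage of the pipeline is validated by recovering what the
generator injected.

## The measurement model

### Dual-reference-arm biometry

A second reference mirror, offset by an optical path `delta_L_ref` from the
retinal reference, folds the corneal reflection into the same imaging window
as the retina. If `d` is the optical-path separation between the foveal RPE
peak and the corneal peak in the composite A-scan, the axial length is

    IOL = (delta_L_ref - d) / n

with `n = 1.3375` the whole-eye group refractive index. The package's
defaults use `delta_L_ref = 35` mm, which places the corneal line a few mm
beyond the zero-delay line for typical adult eyes. `detect_peaks()` takes the
strongest qualifying maximum in the retinal portion of the window (first 40%
of samples) as the foveal peak and the strongest maximum beyond it as the
corneal peak, each refined to subpixel by a parabolic fit; `compute_iol()`
applies the formula. IOL is reported at 3 decimals (µm-scale precision).

### Geographic CT mapping

The 3D pipeline is `correct_motion()` → `segment_volume()` →
`locate_fovea()` → `thickness_normal()` → `sector_summary()` /
`ring_profile()`:

* **Motion correction.** Axial eye motion between B-scans is estimated by
  normalized cross-correlation of laterally averaged axial profiles of
  adjacent B-scans, refined to subpixel by a parabolic fit of the
  correlation peak, chained into a cumulative trace referenced to the first
  B-scan, and applied as integer rolls (no interpolation blur). A caveat
  documented here because it shapes the tests: genuine anatomical depth
  change between B-scans (the curved posterior pole) is indistinguishable
  from slow motion by this estimator, so corrected volumes are slightly
  "flattened" along the slow axis. CT is a within-A-line difference and is
  unaffected; the exact-recovery tests therefore use laterally flat
  phantoms.
* **Segmentation.** Each boundary is a dynamic-programming minimum-cost path
  through a signed vertical-gradient cost (dark-to-bright for ILM and CSI,
  bright-to-dark for the outer RPE) under a per-column step constraint
  (default 2 px). The search runs on log-transformed intensity — under fully
  developed speckle the log makes the noise additive with uniform variance,
  so bright regions no longer dominate the gradient — smoothed by a 5-column
  boxcar and a 1 px axial Gaussian. Subpixel localization then snaps to the
  raw-intensity gradient extremum within 2 px of the path (computed on a
  narrow 3-column support), because the log transform and wide smoothing
  bias edge positions by up to ~1 px while the raw blurred step is
  symmetric, hence unbiased. Columns whose path gradient is weak or whose
  peak intensity is below 5× the noise-floor median are flagged invalid;
  B-scans under 50% valid are dropped; surfaces get a 3×3 median filter and
  the ordering ILM ≤ RPE ≤ CSI is enforced. The dual-analysis 15% rule of
  clinical practice (two operators segment each eye; eyes disagreeing by
  more than 15% are excluded) is provided as
  `segmentation_discrepancy()`; since the automatic pipeline is
  deterministic, `process_eye(dual_qc = TRUE)` emulates the second analysis
  with an alternate smoothing width.
* **Fovea localization.** The fovea is the deepest local depression of the
  ILM. The ILM depth map is smoothed at σ = 0.25 mm and a coarse σ = 1.5 mm
  trend is subtracted before taking the maximum: a quadratic surface (the
  posterior-pole curvature) is invariant up to a constant under both
  smooths, so the bowl of the eye cancels exactly and only the pit survives.
  The centre is refined as the centre of mass of the deepest 5% of pit
  pixels. Maps with relative pit depth under 5 µm raise an error advising a
  manual centre (`fovea_xy` override).
* **Thickness normal to the RPE.** CT is measured along the local normal of
  the Gaussian-smoothed (σ = 0.2 mm) RPE surface in physical units: a ray is
  marched from the RPE point at 0.25-px steps and the first CSI crossing is
  located by linear interpolation; CT is the Euclidean distance. For
  parallel planes tilted by θ this gives exactly `vertical × cos θ`
  (asserted to 1 µm in the tests). Axial pixels are converted to geometric
  µm by dividing the air-path pitch by a tissue index of 1.38 — distinct
  from the whole-eye `n = 1.3375` used for biometry.
* **Geographic summaries.** Sectors follow the 1/5/10 mm concentric grid:
  central fovea (r < 0.5 mm), inner ring (0.5 ≤ r < 2.5) and outer ring
  (2.5 ≤ r < 5), half-open, each ring split into nasal/superior/temporal/
  inferior quadrants by 45° diagonals (pixels exactly on a diagonal go to
  the horizontal quadrants, making the partition deterministic). For left
  eyes the horizontal axis is mirrored so "nasal" always points toward the
  optic disc. The ring profile averages CT in 1 mm annuli inside 90°
  horizontal wedges, giving 11 bins from 5 mm nasal to 5 mm temporal; bin 0
  is the foveal disk. Sectors with under 25% valid area and empty bins are
  flagged missing, never zero.

### Cohort statistics

`assign_group()` classifies by refractive-error magnitude: low ≤ 3 D,
moderate 3–6 D, high ≥ 6 D (boundaries fixed as "−3 D is low", "−6 D is
high"). `group_table()` reports per-group mean ± sample SD (n − 1), pairwise
pooled-variance Student's t-tests (Welch by flag; no multiple-testing
correction is applied, deliberately mirroring common practice in this
literature), and per-diopter reduction rates computed over the 3 D span
between adjacent group midpoints:
`rate = (mean_a − mean_b) / 3`. With the default subfoveal means this yields
31.28 µm/D (low→moderate) and 13.49 µm/D (moderate→high) for CT and
0.265 mm/D (low→moderate) for IOL. For the moderate→high IOL step the same
formula gives (25.983 − 25.413)/3 = 0.190 mm/D; published figures sometimes
quote a different value for this step whose derivation is not reproducible
from the group means, and the package deliberately reports the formula
value.

## The synthetic OCT generator

`make_eye_truth()` draws one eye from group-level parameter distributions;
`render_volume()` and `render_composite_ascan()` turn it into data;
`generate_cohort()` assembles seeded cohorts. The defaults are the study
conditions the package targets: 20 low-myopia, 10 moderate and 10 high
myopia eyes; per-sector CT means ± SDs from the published group table
(low-myopia subfoveal 273.85 ± 49.01 µm, nasal-outer 180.65 ± 58.25 µm,
moderate temporal-inner 194.94 ± 27.78 µm, and so on); IOL means ± SDs of
24.619 ± 0.016 / 25.413 ± 0.022 / 25.983 ± 0.021 mm. They ship as a JSON
file (`inst/extdata/cohort_defaults.json`) read by `default_cohort_spec()`.
Choices the source data leave open, fixed once here:

* **Superior/inferior sectors.** The published table reports only
  nasal/fovea/temporal columns; SIM/IIM (and SOM/IOM) default to the mean of
  the same-ring nasal and temporal values, with SDs averaged likewise.
* **Refractive errors** are sampled uniformly within each group's range
  (−0.25…−3, −3.25…−5.75, −6…−9 D); the within-group distribution is not
  reported anywhere, and uniform is the least-informative choice.
* **The CT field** interpolates the nine drawn sector targets as
  (angular blend) × (radial profile): quadrant values blended with cosine
  transitions of half-width 15° at the diagonals, and a monotone radial
  profile that is flat across the foveal disk, passes the inner/outer
  centroid radii (1.5, 3.75 mm), and is constant beyond the outer centroid.
  A radial-basis interpolant through the nine centroids was considered and
  rejected: it decays or extrapolates arbitrarily outside the centroid ring,
  whereas the nasal-outer value is defined by the data as "the CT 5 mm nasal
  of the fovea", which the plateau construction honours; the foveal plateau
  likewise makes the foveal-disk mean equal the configured subfoveal value
  rather than a blend. The field is clamped at a 20 µm floor, as are the
  sector draws.
* **Geometry.** RPE depth 450 µm with 8 µm/mm² posterior-pole bowing;
  retinal thickness 300 µm; Gaussian foveal pit of depth 110 µm and radius
  0.6 mm, jittered ±0.25 mm so fovea localization is genuinely exercised;
  the CSI sits at distance CT along the local RPE normal.
* **Rendering.** Piecewise-constant reflectivity (vitreous 0.02, retina
  0.25, RPE band 1.0 — the brightest feature — choroid 0.12, 50 µm sclera
  band 0.45) with anti-aliased steps at the boundary positions, blurred by a
  4.25 µm (σ, air) axial PSF; amplitude halves per 3 mm of depth (the 6 dB
  sensitivity roll-off of spectrometer-based OCT); optional unit-mean
  exponential multiplicative speckle (fully developed speckle on intensity);
  per-B-scan integer axial motion uniform in ±4 px; intensities quantized to
  the 16-bit grid so TIFF round trips are bit-exact.
* **Scale.** The default volume is 256 axial samples × 256 A-lines ×
  64 B-scans over ~10 × 5 mm (axial pitch 8 µm air) — a desk-scale version
  of the clinical 512 × 256 protocol, which remains available through
  `render_params()`. At this scale one eye renders and processes in a few
  seconds and a 20-eye cohort pipeline completes in roughly two to three
  minutes; the packaged tests and the acceptance script use 10–20-eye
  cohorts at exactly this geometry.

What the generator does **not** emulate: choroidal vasculature texture and
vessel shadowing, transverse motion and blinks, lateral magnification
differences with axial length, interferogram/k-space effects (dispersion,
fringe washout), and operator variability in semi-automated segmentation.
Passing recovery tests therefore show the pipeline is correct for
layered-geometry images with speckle, roll-off and axial motion — not that
it would segment every pathological clinical scan.

## Numerical choices and degenerate inputs

* Subpixel everywhere is a 3-point parabolic vertex, clamped to ±0.5 px;
  non-convex fits fall back to the integer position. A perfect (ρ = 1)
  correlation peak skips refinement: it is an exact integer shift.
* Cross-correlation ties are broken toward the smaller |lag|; the DP search
  resolves equal-cost transitions toward the smaller |step|.
* Zero-variance profiles return zero shift with a warning; pure noise-floor
  volumes yield all-invalid masks; zero-variance t-test inputs resolve to
  t = 0, p = 1 (equal means) or a degenerate p = 0 flag (unequal).
* The CSI search band is 10–600 µm (air path) below the outer RPE; rays
  that find no CSI crossing within 1000 µm mark their cell invalid.
* Thickness-map cells are `NaN` where invalid, and stay `NaN` through CSV
  round trips.

## Known limitations

* The ring-profile wedge width (90°) and the 3 D reduction-rate span are
  conventions, stated and tested but not uniquely determined by the source
  material.
* Segmentation carries a residual mean CT bias of roughly −2 to +3 µm from
  the interaction of the axial PSF with band edges — an order of magnitude
  below the cohort SDs it is compared against.
* The motion estimator removes smooth anatomical depth trends along the
  slow axis (see above); absolute surface positions after correction are
  accurate only up to that trend, while thickness and fovea localization
  are unaffected.
* `students_t` assumes normality as classical practice does; no
  nonparametric alternative is provided.
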