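# choromap

Geographic choroidal-thickness mapping and simultaneous ocular biometry from
3D spectral-domain OCT volumes.

The choroid — the vascular bed between the retinal pigment epithelium (RPE)
and the sclera — thins progressively with myopia while the eye elongates, and
its thickness profile around the macula is a candidate marker for myopic
degeneration. choromap implements the full measurement chain for studying
this in low (≤ 3 D), moderate (3–6 D) and high (≥ 6 D) myopia:

* **Choroidal thickness (CT)**: segmented from each B-scan as the distance
  from the outer RPE to the choroid–sclera interface, measured along the
  local RPE normal, mapped onto a nine-sector 1/5/10 mm concentric grid
  centred on the fovea (Fovea, then nasal/superior/temporal/inferior inner
  and outer macula: NIM, SIM, TIM, IIM, NOM, SOM, TOM, IOM) and onto a 1 mm
  nasal–temporal ring profile out to 5 mm.
* **Intraocular length (IOL)**: from a composite A-scan in which a second
  reference mirror, offset by ΔL_ref, folds the corneal reflection into the
  retinal imaging window:

      IOL = (ΔL_ref − d) / n,

  where `d` is the optical-path separation between the foveal RPE peak and
  the corneal peak and `n = 1.3375` is the whole-eye group refractive index.
  With ΔL_ref = 35 mm and d = 2.236 mm this gives (35 − 2.236)/1.3375 =
  24.496 mm.

Supporting stages: inter-B-scan axial motion correction by cross-correlation
of B-scan profiles; dynamic-programming boundary segmentation (ILM, outer
RPE, CSI) on log-intensity with subpixel refinement; fovea localization from
the ILM pit; pooled-variance Student's t comparisons and per-diopter
reduction rates across severity groups; and TIFF/JSON/CSV I/O.

Because OCT study scans are rarely shareable, the package includes a
first-class **synthetic OCT generator** (`make_eye_truth()`,
`render_volume()`, `render_composite_ascan()`, `generate_cohort()`) that
emulates the scan protocol (10 × 5 mm macular volumes, speckle, 6 dB/3 mm
sensitivity roll-off, per-B-scan axial motion, dual-reference-arm composite
A-scans) with known ground truth, parameterized by published group-level
sector statistics. Every pipeline stage is validated by recovering injected
truth; see the methods vignette (`vignettes/choromap-methods.Rmd`) for the
model, parameter choices and limitations.

## Worked example

Generate one low-myopia eye, render its volume and composite A-scan, and run
the full measurement chain:

```r
library(choromap)

spec  <- default_cohort_spec()                 # study-condition parameters
truth <- make_eye_truth(spec$low, laterality = "OD", seed = 7,
                        refractive_error = -1.5)
vol   <- render_volume(truth, render_params(), seed = 7)
ascan <- render_composite_ascan(truth)         # delta_L_ref = 35, n = 1.3375

res <- process_eye(vol, ascan = ascan)         # motion -> segment -> map
res$fovea_xy                                   # located foveal pit (mm)
res$iol$iol_mm                                 # measured axial length
res$sectors[, c("sector", "mean_ct_um", "valid_frac")]
```

which prints (R 4.3, default parameters):

```
fovea located at (0.07, -0.10) mm (truth: 0.07, -0.10)
measured IOL: 24.654 mm (truth: 24.654)
  sector mean_ct_um valid_frac
1  Fovea      387.5     0.7954
2    NIM      192.4     0.8216
3    SIM      240.4     0.8493
4    TIM      255.7     0.8377
5    IIM      224.2     0.9022
6    NOM      135.7     0.8554
7    SOM      224.0     0.6106
8    TOM      232.5     0.8483
9    IOM      202.5     0.7203
```

The subfoveal mean (387.5 µm) recovers this eye's drawn ground truth
(385.9 µm) to within a few µm despite speckle and injected motion; the
measured IOL matches the drawn truth to sub-µm. `run_cohort_pipeline()`
applies the same chain to a whole [generate_cohort()] list and
`group_table()` turns the per-eye rows into group mean ± SD tables, pairwise
t-tests and per-diopter reduction rates; `render_ct_map()` draws the sector
means over the en-face fundus projection.

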