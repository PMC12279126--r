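---
title: "Boundary fragment radiomics for periapical lesion healing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boundary fragment radiomics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(apexfa)
```

## The problem

After root canal therapy, the periapical radiolucency of apical
periodontitis (AP) heals over months to years, and clinicians track it with
periapical radiographs taken every few months.  Predicting *how fast* a
given lesion will heal matters for restorative decisions (when to place the
final crown, whether to consider surgery).  The radiographic appearance of
the *lesion boundary* — sharply demarcated, blurred, or corticated — is an
established qualitative prognostic cue; `apexfa` turns it into numbers.

The pipeline has four stages:

1. **Segmentation** — Canny edge detection (`canny()`) followed by
   deterministic seeded contour tracing (`trace_contour()`) yields a closed
   lesion contour.  Three regions of interest follow (`build_rois()`):
   S1 = interior eroded clear of the edge, S2 = interior dilated to include
   the edge, S3 = S2 minus S1 (the boundary annulus).
2. **Fragment analysis (FA)** — the grayscale transition zone from
   radiolucent interior to radiopaque bone is located along boundary
   normals (`locate_transition()`), tiled with oriented 1 mm x 1 mm squares
   centred on the zone (`tile_boundary()`), and the square fragments are
   resampled with the lesion interior on the left and concatenated into the
   striped boundary image S4 (`extract_fragments()`, `reassemble()`).
3. **Texture and rad-score** — MaZda-convention histogram, GLCM
   (`S(d,theta)` statistics) and GLRLM features over S1–S4
   (`extract_all()`); LASSO-penalized Cox regression selects boundary
   signatures and weights them into a radiomics score
   (`build_rad_score()`, `rad_score()`), validated by optimal-cutpoint
   stratification, Kaplan–Meier curves and the G-rho weighted log-rank
   test.
4. **Prognostic models and evaluation** — multivariate Cox models (clinical
   reference vs clinical + rad-score; `fit_cox()`, `stepwise_select()`,
   `bootstrap_validate()`), evaluated on a held-out cohort with
   time-dependent IPCW ROC/AUC, paired AUC comparison, fixed-time
   calibration and decision curves (`time_dependent_roc()`,
   `compare_auc()`, `calibration_at_time()`, `decision_curve()`).

Why reassemble the boundary at all?  GLCM and GLRLM features count
gray-level co-occurrences along *fixed image directions*, so on the raw
radiograph they are sensitive to how the lesion happens to be oriented.  In
S4 every fragment is co-registered — columns run across the boundary,
rows along it — so direction-dependent statistics become *boundary-relative*:
`S(5,0)Contrast` on S4 reads "contrast across the lesion margin at a 5-pixel
offset" regardless of how the tooth was positioned on the sensor.  The test
suite demonstrates this directly: rotating the whole radiograph by 90
degrees leaves S4 features unchanged to within interpolation tolerance while
interior (S1) features of an anisotropic lesion change substantially.

## The synthetic phantom and cohort

No public radiograph set with healing follow-up exists, so the package
ships a generator that emulates the features the method consumes, with
known ground truth.

`generate_phantom()` renders an elliptical radiolucency whose radial
profile follows a logistic sigmoid from `interior_level` (default 60) to
`exterior_level` (default 140).  The **transition width** is defined as the
10%–90% rise distance in mm — the radiological "grayscale gradient
transition zone" made measurable.  Options add a corticated rim (a Gaussian
overshoot just outside the edge), band-limited trabecular background
texture, white pixel noise, and oriented interior stripes (used to build
anisotropic test cases).  Defaults: 0.1 mm/pixel (one FA square = 10 x 10
px), lesion diameters restricted to the clinical inclusion range 5–15 mm.

`generate_cohort()` draws six clinical covariates at frequencies typical of
an endodontic case mix (age ~52 +/- 19, ~38% female, ~30% diabetic, lesion
~10 +/- 3.3 mm, ~65% mandibular, anterior/premolar/molar 28/28/44%) and a
per-patient transition width uniform on 0.2–0.8 mm.  Healing times follow a
Weibull proportional-hazards model (shape 1.6, scale 24 months, so the
baseline median is ~19 months) whose linear predictor combines the clinical
coefficients with standardized boundary *sharpness* `1/width`
(`beta_boundary = -1.3` by default: sharply demarcated lesions heal more
slowly, blurred "acute" boundaries faster).  Healing is only observed at
3-month radiograph visits, so observed event times are rounded **up** to
the next visit; censoring occurs at 36 months or at a geometric dropout
visit (per-visit probability 0.015).  Patients are split 6:4 into
development and validation cohorts.

What the phantoms do **not** emulate: projection physics, anatomical
superimposition (e.g. the maxillary sinus, an exclusion criterion
clinically), scanner-specific gray-level calibration, and operator
variability in seeding the contour.  Green tests therefore show that the
*computational chain* is correct and that the statistical machinery behaves
as specified — not that the method is validated on clinical radiographs.

## Numerical and design choices

* **Coordinates** are 1-based `(row, col)` with pixel centres at integers —
  the R convention; masks align with the pixel matrix.
* **Canny**: gradients are central differences (units: gray levels per
  pixel), images above 255 are rescaled to 0–255 so the conventional 35/50
  double threshold is bit-depth independent.  The *pipeline default* for
  phantoms is low = 4 / high = 8: the generator's default contrast (80 gray
  levels over up to 0.8 mm) gives edge gradients of roughly 9–44 gray/px,
  so the 35/50 scanner-calibrated values would miss blurred boundaries.
  `sigma = 1.4` px, unstated by convention elsewhere, is exposed as
  configuration.
* **Threshold fallback**: if no closed contour is recoverable at the
  configured thresholds (very blurred boundaries can locally drop below
  them), `process_radiograph()` relaxes them deterministically to 75% and
  then 50% before reporting failure — the automated counterpart of an
  operator re-tuning the detector on a low-contrast film.
* **Contouring** replaces operator-guided semi-automatic contouring with
  morphological gap closing (radius 0.3 mm, grown to 1 mm if needed),
  seed-component extraction and periodic smoothing; the seed point plays the
  operator's role.  The traced region is dilated one pixel so the contour
  follows the centre of the 1-px edge line.
* **Transition centerline smoothing** uses a 1-sample periodic Gaussian: a
  wider window shrinks a closed curve by ~sigma^2/2r, which at the 5 mm
  minimum lesion is enough to change the square count.
* **Tiling closure.**  Marching 1 mm chords around a closed centerline
  rarely closes exactly.  The default `closure = "distribute"` picks the
  integer square count nearest the exact chord count and adjusts the
  marching chord by at most about half a square so the ring closes
  symmetrically; `closure = "drop"` marches exact 1 mm chords and drops the
  final square, leaving the mismatch at one joint.
* **Tiling geometry is intrinsically approximate.**  Consecutive squares on
  a curved boundary tilt by `phi = 2 asin(side/2R)` per joint, so rigid
  non-overlapping squares cannot cover the band exactly: with seams
  crossing at the centerline, either an outer sliver (total ~ pi w^2 / 4
  over the whole ring) is missed or an inner sliver (~phi/8 mm^2 per seam)
  is doubly covered.  At 10 mm diameter these slivers are sub-pixel; at the
  5 mm inclusion limit phi is 23 degrees and the seam wedge reaches ~6
  px^2 — the method's own reason for excluding lesions below 5 mm.
  Coverage is therefore measured cell-wise (a band pixel counts as covered
  when its 1-px cell meets the square union), and the quality report
  (`tiling_qc()`) separates non-consecutive overlap (must be exactly zero)
  from consecutive seam wedges.
* **Fragments** are resampled by bilinear interpolation in each square's
  own frame (squares sit at arbitrary angles); the interior-on-left
  orientation co-registers all fragments, and ordering starts at the
  topmost centerline point proceeding clockwise.  Any fixed convention
  works: GLCM features of S4 are order-sensitive only at fragment seams.
  GLCM pairs on S4 deliberately *include* seam-straddling pairs — the
  reassembled picture is analysed as-is, and seam sensitivity is a known
  property of the method.
* **Quantization**: gray levels are clipped to `mu +/- 3 sigma` over the
  ROI (intersected with the observed range, so a wide clip degrades to
  min–max binning) and binned to G = 64 levels — MaZda-convention defaults.
  Features are invariant to adding a constant gray level.
* **LASSO-Cox**: Breslow ties throughout; features standardized inside the
  fit; ten-fold cross-validation stratified by event; the selection rule is
  the deviance-minimizing penalty (`rule = "min"`, matching a single
  reported penalty per model).  The conservative `"1se"` rule is also
  available; under pure noise `"min"` occasionally admits a stray feature
  (median zero), while `"1se"` selects nothing in most replicates — both
  behaviours are asserted in the tests.
* **Optimal cutpoint** reconstructs point-and-click cutpoint software as an
  exhaustive log-rank scan over score midpoints with a 10% minimum-group
  constraint, with the Miller–Siegmund correction reported because the
  maximally selected chi-square is anti-conservative.
* **Time-dependent ROC** uses the cumulative-case/dynamic-control
  definition with IPCW weights from the censoring Kaplan–Meier of the
  evaluation cohort; the SE comes from the influence-function (DeLong-type)
  representation of the weighted two-sample statistic, and the paired model
  comparison uses the joint influence covariance — the time-dependent
  analogue of the DeLong test, which is undefined verbatim under censoring.
* **Calibration** is decile-binned observed (bin Kaplan–Meier at t) versus
  mean predicted risk with least-squares slope/intercept; empty bins merge
  into their neighbour.  **Decision curves** use the standard net-benefit
  formula with the event probability inside the treated group estimated by
  Kaplan–Meier at t; the threshold grid is 0.01–0.99.
* **Models**: the reference model uses the six clinical covariates (gender,
  age, diabetes, lesion diameter, position, location as two dummies);
  model k adds the S_k rad-score as a continuous covariate (group mode is
  available via the cutpoint).  Stepwise selection is backward by AIC;
  internal validation is Harrell's optimism bootstrap.  Model 1 (interior
  rad-score) is constructible but is the variant expected to validate
  poorly.

## Problem sizes

The shipped configuration runs the full synthetic study at n = 250 patients
(6:4 split, images ~160–210 px square at 0.1 mm/px), which takes about two
minutes on one CPU; the test suite uses the same size for the end-to-end
check and smaller cohorts (n = 24) for orchestration smoke tests.
Simulation-based statistical tests use up to n = 2000 subjects (tables
only, no images) and a few hundred replicates.

## Known limitations

* Single lesion per image; open (non-closed) boundaries are out of scope.
* The phantom gray-level scale is not calibrated to any particular scanner;
  intensity statistics are free parameters of the generator.
* GLCM/GLRLM feature sets cover the standard histogram + co-occurrence +
  run-length families; wavelet/autoregressive/gradient families are not
  implemented.
* At the 5 mm minimum lesion diameter the 1 mm tiling geometry is at its
  feasibility edge (see above); quality metrics make this visible rather
  than hiding it.
* DICOM input is not supported; use PNG/TIFF with the JSON spacing sidecar.
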