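# apexfa

Boundary fragment radiomics for predicting the healing time of periapical
lesions on dental radiographs.

## The problem

Apical periodontitis (AP) appears on a periapical radiograph as a
radiolucent lesion around the root apex. After root canal therapy the
lesion heals over months to years, monitored with radiographs every few
months; the healing *speed* informs restorative decisions. Radiologists
read prognosis partly from the **lesion boundary** — sharply demarcated,
blurred, or corticated — but that reading is qualitative. `apexfa`
quantifies it.

## The method

The core is **fragment analysis (FA)** of the boundary:

1. **Canny edge detection** (Gaussian smoothing, gradient, non-maximum
   suppression, 35/50 double-threshold hysteresis) plus deterministic
   seeded contour tracing gives a closed lesion contour, from which three
   regions of interest are built: S1 (interior eroded clear of the edge),
   S2 (interior dilated over the edge), S3 = S2 − S1 (the edge annulus).
2. The **grayscale transition zone** — the band over which intensity rises
   from radiolucent interior to radiopaque bone — is located along boundary
   normals; its centerline is the 50% intensity crossing and its local
   width the 10%–90% rise distance.
3. The centerline is tiled with **1 mm × 1 mm squares**, each centred on
   the transition zone with one side parallel to the local boundary
   tangent; squares must not overlap but touch. Each square's content is
   resampled with the lesion interior on the left, and the fragments are
   concatenated into the striped image **S4**.
4. MaZda-convention texture features — histogram statistics, GLCM
   `S(d,θ)` statistics for d ∈ 1..5 and θ ∈ {0°,45°,90°,135°}, and GLRLM
   run statistics — are extracted from S1–S4. Because S4 is
   boundary-relative, direction-dependent features such as `S(5,0)Contrast`
   measure texture *across the lesion margin* regardless of lesion
   orientation in the image.
5. A **LASSO-penalized Cox** model (10-fold cross-validated deviance)
   selects boundary signatures; the **rad-score** is
   `Σ_j β_j · (x_j − μ_j)/σ_j` over the selected features. Patients are
   stratified at an optimal cutpoint (exhaustive log-rank scan) and
   validated by Kaplan–Meier curves with the G-rho (ρ = 1) weighted
   log-rank test and univariate Cox hazard ratios.
6. Multivariate **Cox models** (clinical reference: gender, age, diabetes,
   lesion diameter, tooth position, tooth location; plus rad-score
   variants) are evaluated on a held-out cohort with time-dependent IPCW
   ROC/AUC at 12/15/18 months, influence-function paired AUC comparison,
   fixed-time calibration slope/intercept, and decision-curve analysis.

Because no public AP radiograph cohort with follow-up exists, the package
also ships a **synthetic generator**: elliptical lesion phantoms with a
tunable sigmoid transition zone, optional corticated rim, trabecular
background texture, and Weibull proportional-hazards healing times observed
on a 3-month radiograph grid — so the whole pipeline runs end to end with
known ground truth.

## Worked example

```r
library(apexfa)

# one synthetic lesion: 10 mm diameter, 0.5 mm transition zone
ph <- generate_phantom(phantom_params(lesion_diameter = 10,
                                      transition_width = 0.5))
edges   <- canny(ph$image, low = 4, high = 8)   # generator-contrast thresholds
contour <- trace_contour(edges, c(110.5, 110.5), spacing = 0.1)
band    <- locate_transition(ph$image, contour)
tiling  <- tile_boundary(band)
s4      <- reassemble(extract_fragments(ph$image, tiling))
tiling
#> <boundary_tiling: 31 squares of 1.0 mm (10.0 px)>
s4
#> <s4_image: 10 x 310 px (31 fragments)>
median(band$local_width)
#> [1] 0.5135612
```

A 10 mm circular lesion has perimeter π·10 ≈ 31.4 mm, so 31 one-millimetre
squares tile its boundary; the measured transition width recovers the
simulated 0.5 mm within ~3%. The full synthetic study:

```r
res <- run_study(pipeline_config())   # 250 patients, 6:4 split, ~2 min
subset(res$metrics, t == 15)
#>      model  t       auc    auc_lo    auc_hi cal_slope cal_intercept
#>  reference 15 0.5327297 0.4129300 0.6525294 0.3127314    0.37887114
#>     model1 15 0.6911042 0.5818421 0.8003663 0.7949291    0.17892986
#>     model2 15 0.7864449 0.6901399 0.8827499 0.8844900    0.08503211
#>     model3 15 0.7760771 0.6777449 0.8744092 0.8237320    0.11647246
#>     model4 15 0.7805814 0.6820315 0.8791313 0.8075930    0.11852481
```

The clinical-only reference model barely discriminates (validation AUC
≈ 0.53 at 15 months), while adding the S4 boundary rad-score lifts the AUC
to ≈ 0.78 with a calibration slope much closer to 1 — the boundary carries
the prognostic signal, and fragment analysis extracts it. (The ceiling
under these simulation settings, using the true linear predictor, is AUC
≈ 0.82.)

A command-line front end wraps the same stages:

```sh
Rscript inst/cli/apexfa.R simulate --n 60 --out demo_run
Rscript inst/cli/apexfa.R pipeline --out demo_run_full
```

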