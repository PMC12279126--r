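Package: apexfa
Title: Boundary Fragment Radiomics for Predicting Periapical Lesion Healing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the boundary of periapical (apical periodontitis)
    lesions on 2-D dental radiographs and predicts radiographic healing time
    with survival models.  Implements Canny edge detection and deterministic
    lesion contouring, construction of interior/extended/annulus regions of
    interest (S1-S3), and fragment analysis (FA): the grayscale transition
    zone at the lesion margin is tiled with oriented 1 mm squares whose
    fragments are reassembled into a boundary-relative striped image (S4).
    MaZda-convention histogram, gray-level co-occurrence (GLCM) and
    run-length (GLRLM) texture features feed a LASSO-penalized Cox
    radiomics score, risk stratification with G-rho weighted log-rank
    validation, multivariate Cox models, and time-dependent evaluation
    (IPCW ROC/AUC with paired comparison, fixed-time calibration, and
    decision-curve analysis).  A synthetic phantom and cohort generator
    provides radiographs and right-censored healing outcomes with known
    ground truth, so the whole pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    glmnet,
    jsonlite,
    png,
    stats,
    survival,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
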