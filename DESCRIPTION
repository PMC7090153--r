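Package: skinNTCP
Title: Dose-Surface Histogram NTCP Modeling of Severe Radiation Dermatitis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for normal tissue complication probability
    (NTCP) modeling of severe acute radiation dermatitis from skin
    dose-surface histograms (DSH). Provides automatic skin segmentation of
    CT-like volumes by thresholded body-contour correction and anisotropic
    morphological erosion, DSH extraction as the thin-shell limit of the
    dose-volume histogram with body-surface-area normalization, cohort
    univariable statistics with Holm-Sidak multiple-comparison control,
    maximum-likelihood fitting of the DSH-recast Lyman-Kutcher-Burman model
    with profile-likelihood confidence intervals, multivariable stepwise
    logistic NTCP modeling, and leave-one-out validation with ROC,
    Youden-cutoff, balanced-accuracy and calibration summaries. Includes a
    synthetic phantom and cohort generator so the full chain is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    RNifti
Config/testthat/edition: 3
RoxygenNote: 7.3.3
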