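Package: radheight
Title: Radiomic Knee Scores and Final-Height Prediction for Girls at Menarche
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for predicting adult height of post-menarcheal girls from
    knee radiographs and clinical covariates. Extracts 2D radiomic features
    (first-order, shape, GLCM, GLRLM, GLSZM, GLDM, NGTDM) from annotated
    epiphyseal regions under original and wavelet-filtered images, reduces them
    by an ICC reliability gate, variance threshold, univariate screen and LASSO,
    and summarises the surviving features as a signed-log radiomic score.
    Builds stepwise ordinary least squares prediction equations from clinical
    and imaging predictors, and benchmarks them against Bayley-Pinneau bone-age
    projection and mid-parental target height using five-fold cross-validation,
    RMSE/RPD, residual buckets and Bland-Altman agreement. Includes a seeded
    synthetic-cohort generator (clinical tables plus procedural epiphysis
    images) so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    MASS,
    png,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
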