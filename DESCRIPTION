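Package: spectralPCa
Title: Spectral and Statistical Assessment of Prostate Cancer from
    Biparametric MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for covariance-based spectral analysis of spatially
    registered biparametric prostate MRI (ADC, high b-value, T2).
    Assembles a registered three-band image cube from per-sequence
    volumes, estimates the normal-prostate background distribution with
    principal-component filtering and shrinkage regularization, scores
    voxels with the adaptive cosine estimator (ACE), derives per-patient
    z-score and signal-to-clutter ratio (SCR) metrics, measures tumor
    blob volume and eccentricity by 3D connected-component morphometrics,
    calibrates external detector likelihoods to ISUP grade, and provides
    the univariate/multivariate regression and randomized-split AUROC
    statistical layer. A synthetic-cohort generator with planted
    grade-dependent lesions supports end-to-end validation without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
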