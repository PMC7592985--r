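Package: pzrad
Title: Voxel-Wise Radiomic Classification of Peripheral Zone Prostate Cancer
    from Multiparametric MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for voxel-based classification of peripheral zone
    prostate cancer from noncontrast multiparametric MRI (T2-weighted,
    high-b-value diffusion-weighted, ADC, and diffusion tensor eigenvalue
    volumes). Implements reference-tissue intensity standardization,
    per-voxel extraction of 191 radiomic features (first-order, gray-level
    co-occurrence, edge, gradient, and diffusion tensor scalar maps),
    correlation-based feature selection, Gaussian-process Bayesian
    optimization of a radial-basis-function support vector machine,
    leave-one-patient-out validation, and Platt-calibrated cancer
    probability maps, together with a seeded synthetic phantom cohort
    generator used to exercise the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    Rcpp,
    e1071,
    lhs,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
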