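Package: noderad
Title: Interpretable Radiomics for Lymph-Node Status Prediction on CT
Version: 0.1.0
Authors@R: person("noderad", "developers", role = c("aut", "cre"),
    email = "noderad@example.org")
Description: An interpretable radiomics pipeline for classifying contoured
    lymph nodes on contrast-enhanced CT as normal, metastatic, or showing
    extranodal extension (ENE). The package normalizes CT slices, refines
    contour masks, derives geometric primitives (largest section, inscribed
    square, boundary bands, isotropic 3D surface model), extracts a fixed
    catalog of 460 features in 26 subsets (GLCM and GLSZM texture,
    gray-level statistics, 2D/3D morphology, boundary contrast, Hu
    invariant moments), ranks feature subsets by cross-validated SVM
    accuracy, runs an inheritable bi-objective combinatorial genetic
    algorithm (IBCGA) with orthogonal-array crossover that co-optimizes
    binary feature selection and SVM (C, gamma), and predicts node status
    with a 31-member voting ensemble. A synthetic phantom generator makes
    the whole pipeline testable without clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
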