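Package: idlelung
Title: Integrated Deep Learning Evaluation of Lung Cancer Progression Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements an integrated deep learning evaluation (IDLE) pipeline
    for progression-risk prediction in completely resected stage IA non-small-cell
    lung cancer. Covers handcrafted 3D radiomics extraction from low-dose CT
    volumes (nested intensity-weighted centroid dispersion, first-order,
    gray-level co-occurrence and run-length texture families over intra-, peri-
    and extra-tumor volumes of interest), encoding of pathologist slide readings
    into tissue features, a hybrid multilayer-perceptron / random survival
    forest risk score evaluated by leave-one-patient-out cross-validation,
    time-dependent ROC / predictive-value statistics under censoring,
    risk stratification and Cox added-value analysis, and decoding of the
    fitted network through feature-selection frequencies and univariate
    screens. A synthetic-cohort generator provides CT phantoms, reading
    tables and survival outcomes with controllable cross-platform signal so
    the full pipeline can be exercised and tested end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ranger,
    survival,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    RNifti,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
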