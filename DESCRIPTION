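Package: milcta
Title: Attention-Based Multiple Instance Learning for Coronary Stenosis
    Detection on CT Angiography Reformations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects significant (>=50%) coronary artery stenosis from stacks
    of curved multiplanar reformation (CMR) slices using weakly supervised
    multiple instance learning. Implements a multi-attenuation-window
    preprocessing pipeline (Hounsfield-unit windowing, Sobel edge extraction,
    maximum-response fusion, small-object and burned-in-text removal,
    connected-component ranking), 36-slice bag construction with replication
    padding, leakage-free stratified patient-level splits, an attention-based
    bag classifier with sinusoidal positional encoding, multi-head
    self-attention and gated attention pooling, and a patient-level
    evaluation stack (ROC AUC with confidence intervals across repeats,
    Brier score, calibration tables, threshold sweeps). A synthetic-cohort
    generator with known slice-level ground truth makes the whole pipeline
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
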