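Package: restconn
Title: Resting-State Functional Connectivity Analysis and Expertise Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reproducible pipeline for group analysis of
    resting-state functional connectivity from region-of-interest (ROI)
    BOLD time series: frame-wise displacement computation and
    cohort-uniform volume censoring, anatomical component-based (CompCor)
    nuisance regression with detrended motion parameters, zero-phase
    bandpass filtering, PCA-based ROI signal extraction, Pearson/Fisher-z
    connectivity matrices over a 112-region parcellation, edge-wise
    label-permutation group tests, edge-score correlations, and a
    t-ranked sequential feature-addition linear SVM classifier evaluated
    by leave-one-out cross-validation. Includes a synthetic two-group
    cohort generator with known injected edge effects, motion spikes,
    nuisance structure and score coupling, so that every stage can be
    validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    RNifti,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
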