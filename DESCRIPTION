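Package: fcstates
Title: Brain-State Discrimination from Functional Connectivity Network Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates functional-connectivity network matrices from
    multi-node physiological time series under configurable dependency
    measures (amplitude, covariance, full correlation with Fisher z,
    Tikhonov/ridge-regularized partial correlation) and spectral filters
    (order-4 zero-phase Butterworth band/high-pass, Welch power spectral
    density), classifies brain states with leave-one-subject-out
    cross-validation (multiclass linear SVM with nested regularization
    selection, optional k-NN), and compares pipeline variants with
    McNemar, Wilcoxon signed-rank and Benjamini-Hochberg FDR statistics.
    Includes a synthetic multi-subject, multi-state generator with
    ground-truth sparse precision structure, state-dependent amplitudes
    and frequency-band-specific couplings, so the full pipeline is
    testable without access to raw neuroimaging recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    RNifti
Config/testthat/edition: 3
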