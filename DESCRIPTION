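Package: smatpase
Title: Single-Molecule Fluorescent-ATP Turnover Analysis for Myosin on Actin
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for single-molecule TIRF recordings of
    fluorescent nucleotide turnover by actin-bound myosin motor fragments.
    Provides an exact (Gillespie) stochastic simulator of per-ROI binding and
    turnover events, camera frame-integration and threshold-based dwell-time
    measurement, a synthetic two-channel movie generator with ground truth,
    event detection and selection criteria for intensity traces, cumulative
    dwell-time distributions with multi-exponential nonlinear fitting, AICc
    model comparison and amplitude corrections, eGFP-based motor density
    quantification on filaments, and Monte-Carlo studies of digitization bias
    and sampling variability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
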