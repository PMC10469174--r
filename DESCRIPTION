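Package: stilflow
Title: Stromal Tumor-Infiltrating Lymphocyte Scoring, Reader Agreement, and
    Assisted-Revision Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies stromal tumor-infiltrating lymphocytes (sTIL) from
    cell detections and tissue segmentations via a normalized count-over-area
    score with a calibrated proportionality constant; simulates whole-slide
    tissue maps, spatially heterogeneous lymphoid point patterns, pathologist
    raters and an error-prone automated reader; computes multi-reader
    agreement statistics (Lin's concordance correlation coefficient with
    confidence intervals, per-case coefficient of variation, nonparametric
    Bland-Altman limits, exact McNemar test); implements the
    ten-percentage-point triage and assisted-revision workflow with full
    revisit/rescore accounting; and relates sTIL strata to neoadjuvant
    chemotherapy response via Miller-Payne dichotomization and binary
    logistic regression fit by iteratively reweighted least squares.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
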