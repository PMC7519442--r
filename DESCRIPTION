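Package: tissuerte
Title: Tissue Distribution Quantification and Relative Targeting
    Efficiency from LC-MS/MS Peak Areas
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for multi-tissue drug distribution studies that
    quantify compounds by LC-MS/MS internal-standard peak-area ratios.
    Fits 1/x^2 weighted linear calibration curves with LLOQ/LLOD
    determination, computes the full bioanalytical method-validation
    report (precision, accuracy, extraction recovery, matrix effect,
    four-condition stability), converts study peak areas into
    concentration-time profiles under a destructive sparse-sampling
    design, estimates tissue AUC by the linear trapezoid with Bailer's
    sparse-sampling standard error, compares treatment groups, and
    derives the relative targeting efficiency (RTE) statistic that
    measures how a processing step shifts a compound's share of total
    multi-tissue exposure. Includes a synthetic-study generator with
    known kinetic ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
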