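Package: urinePAGE
Title: Densitometric Evaluation of Urinary Protein SDS-PAGE Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of one-dimensional SDS-PAGE separations of urinary
    proteins on gradient gels: simulation of Coomassie-stained gel lanes
    with known composition, densitometric lane-profile extraction,
    background subtraction and band detection, molecular-weight
    calibration with internal-standard correction, annotation of bands
    against a packaged indicator-protein reference, rule-based
    classification of proteinuria patterns (glomerular, "upper" and
    "lower" tubular, mixed, overload), semiquantitative concentration
    estimation with a limit of detection, and cohort-level contingency
    statistics with expected-count-based routing between the Pearson
    chi-square and Fisher exact tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    minpack.lm,
    withr,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
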