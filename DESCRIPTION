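Package: chemscreen
Title: Chemical-Genetic Interaction Screening and Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for chemical-genetic interaction screens in
    yeast: per-plate colony fitness and Z-score normalization for arrayed
    solid-medium screens, growth-curve (OD600) validation with logistic fits
    and AUC-based fitness under a multiplicative interaction model,
    overexpression suppression analysis, and simplified synthetic genetic
    array (SGA) scoring of double mutants. Includes statistical primitives
    (Welch's t-test, Benjamini-Hochberg correction, trapezoidal AUC, logistic
    growth fitting) and a synthetic-data generator with known ground truth
    for calibration and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
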