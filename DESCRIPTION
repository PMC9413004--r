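Package: taguchigra
Title: Taguchi Orthogonal-Array Design and Grey Relational Analysis for
    Multi-Response Bioprocess Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing Taguchi L18 orthogonal-array experiments with
    one or several larger-the-better responses, built around a chitosan-driven
    flocculation and biocontrol case study. Provides the L18(3^5) design with
    balance checking, larger-the-better signal-to-noise conversion, balanced
    fixed-effects ANOVA of signal-to-noise ratios, main-effects analysis with
    optimal-level selection and additive prediction, grey relational analysis
    (normalization, deviation sequences, grey relational coefficients and
    grades, ranking, and scoring of out-of-design validation runs), a synthetic
    designed-experiment generator with planted factor effects for recovery
    studies, packaged study fixtures, CSV import/export and plain-text reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
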