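Package: metaexpr
Title: Cross-Study Meta-Analysis and Meta-Regression of Differential Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Synthesizes two-arm differential-expression microarray studies with
    inverse-variance weighted random-effects meta-analysis. Computes per-gene log
    expression ratio (lnR) effect sizes and their sampling variances from replicate-
    level log2 expression matrices, estimates between-study variance by restricted
    maximum likelihood or the DerSimonian-Laird moment estimator, fits per-gene
    mixed-effects meta-regression with categorical moderators (plant part, water
    stress method) tested by the Q_M statistic, adjusts genome-wide p-values by the
    Benjamini-Hochberg step-up procedure, and compares the synthesis against
    per-study moderated t-tests with empirical-Bayes variance shrinkage. Includes a
    multi-study simulator with known ground truth for calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    limma,
    jsonlite,
    optparse
Config/testthat/edition: 3
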