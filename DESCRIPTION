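Package: immunoconcord
Title: Concordance Analysis of Automated Immune Scoring Versus Pathologist
    Visual Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing automated percentile-based immune scoring
    (Immunoscore-style classification of CD3+ and CD8+ T-cell densities in the
    tumor center and invasive margin) against pathologist visual T-score
    assessment in colon cancer. Provides percentile conversion against a
    reference cohort with clinical cutoff classification, stratified case
    selection across the score range, Cohen and Fleiss kappa agreement
    statistics with qualitative interpretation bands, positive and negative
    percent agreement, repeatability analysis of repeated automated
    measurements, a configurable simulator of cohorts and of rater panels
    before and after a training intervention, and a clinical decision-tree
    model propagating misclassification rates to under- and over-treatment
    estimates in stage II/III colon cancer populations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071
Config/testthat/edition: 3
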