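Package: rakenorm
Title: Post-Stratification Raking Weights and Continuous Norming of Psychometric Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Weighted norming workflow for psychometric tests: computes
    post-stratification case weights by raking (iterative proportional
    fitting) of a normative sample against population marginals, derives
    norm scores by weighted rank-based inverse normal transformation per
    age group, and fits continuous regression-based norm models
    (polynomials in person location and age with exact best-subset term
    selection). Includes norm-table and percentile-curve generation,
    model consistency checking, and a synthetic normative-sample
    generator with known ground truth for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
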