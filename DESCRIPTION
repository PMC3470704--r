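Package: heterochron
Title: Detection of Transcriptional Heterochrony in Gene Expression Age-Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and characterizes timing differences ("heterochrony") in
    gene-expression change with age between two groups of individuals. Provides
    a per-gene statistical cascade (polynomial age-effect test selected by
    adjusted R-squared, ANCOVA trajectory-divergence test, co-direction filter),
    a dynamic-time-warping shift test with open-ended alignment and
    simulation-based significance run in both alignment directions, a
    nonlinear-least-squares alternative shift estimator, and downstream
    analyses (Cohen's d effect sizes residualized against age correlation,
    residual variance F-tests, hypergeometric set-overlap statistics,
    trajectory clustering, and bootstrap sample clustering). A synthetic-data
    generator emulates two-group expression age-series with planted
    age-related, divergent and heterochronic genes so every stage can be
    exercised and calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    limma,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
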