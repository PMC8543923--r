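Package: netdbt
Title: Global Inconsistency Assessment for Network Meta-Analysis via the
    Design-by-Treatment Interaction Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Contrast-based network meta-analysis of dichotomous outcomes
    with a frequentist generalized-least-squares engine: study-level log
    odds-ratio contrasts with exact multi-arm covariance, consistency and
    design-by-treatment (DBT) interaction models, DerSimonian-Laird and
    restricted maximum likelihood estimation of a common between-study
    variance, Cochran's Q with its within- and between-design
    decomposition, and the global Wald chi-squared test of inconsistency.
    Includes structural network metrics (designs, loops, inconsistency
    degrees of freedom), a batch survey pipeline that tabulates the
    prevalence of evidence of inconsistency across collections of
    networks, and a synthetic trial-network generator with Monte-Carlo
    harnesses for type-I error, power, and heterogeneity recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    metafor,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
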