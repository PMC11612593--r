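Package: aidpatterns
Title: Temporal Pattern Discovery in Automated Insulin Delivery Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering expected and unexpected temporal patterns in
    insulin-need time series recorded by automated insulin delivery (AID)
    systems. Provides a synthetic cohort generator with plantable effects,
    hourly resampling and eligibility filtering of irregular device logs,
    pairwise mean-difference testing at several temporal granularities under
    Bonferroni family-wise error control with effect sizes and power analysis,
    a taxonomy classifier for expected (E1-E3) and unexpected (U1-U2) insulin
    need patterns, k-means clustering of diurnal multivariate profiles,
    matrix-profile motif and discord discovery, Kendall tau association of
    pattern frequencies with demographic and device factors, and pairwise
    Granger-causality analysis of forecastability.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    lmtest,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
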