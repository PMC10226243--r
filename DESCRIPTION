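Package: survmature
Title: Survival Extrapolation Accuracy Under Artificial Database Locks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to study how the maturity of right-censored survival data
    affects the accuracy of parametric extrapolation. Simulates staggered
    enrollment cohorts with multiple-myeloma-like overall-survival hazards,
    constructs database locks of increasing maximum follow-up, fits the seven
    standard parametric families and Royston-Parmar flexible spline models by
    censored maximum likelihood, and quantifies lifetime, restricted and
    conditional restricted mean survival time (RMST) error against the
    long-follow-up Kaplan-Meier estimate, stratified by censoring percentage,
    event count and model class.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    flexsurv,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
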