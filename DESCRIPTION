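Package: hierpower
Title: Analytic Power for Balanced Multilevel Randomized Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Exact analytic power for the mixed-model Wald test with
    Kenward-Roger degrees of freedom in balanced multilevel randomized
    controlled trials, computed through power-equivalent independent
    sampling unit level multivariate linear models (Hotelling-Lawley
    trace with the McKeon F reference distribution). Supports a
    four-level Gaussian hierarchy (participants within providers within
    clinics within hospitals) with a three-level exchangeable
    intraclass-correlation covariance model crossed with an unstructured
    outcome covariance, randomization at any of the four levels,
    unweighted-composite and multivariate endpoints, and pooled versus
    stratified subgroup analyses. Includes a full-trial Monte-Carlo
    simulator whose aligned cluster-mean tests serve as an independent
    empirical check on every analytic power value.
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
    ggplot2,
    jsonlite,
    optparse
Config/testthat/edition: 3
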