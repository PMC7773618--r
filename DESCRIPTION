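Package: neckloop
Title: Closed-Loop Active Cervical Muscle Simulation of Head-Neck Rear-Impact Response
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates sagittal head-neck kinematics in low-severity rear impacts
    with a rigid-link cervical spine surrogate driven by prescribed T1 motion,
    Hill-type line muscles, and a delayed proportional-derivative reflex
    controller with spatial-tuning recruitment (angular-positioned feedback).
    Provides curve-mapping and CORA-style curve-agreement metrics, metamodel
    (sequential response surface) and genetic-algorithm parameter
    identification of the six controller constants, a synthetic rear-impact
    pulse and volunteer-surrogate target generator, and an end-to-end study
    replay driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    lhs,
    signal,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
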