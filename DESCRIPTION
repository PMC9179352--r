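Package: ablateCEA
Title: Cost-Effectiveness Modelling of Extended Percutaneous Ablation in
    Cirrhotic Hepatocellular Carcinoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating the extended use of percutaneous ablation
    against standard-of-care management of hepatocellular carcinoma on
    cirrhosis: synthetic patient-level cohort generation calibrated to a
    matched two-centre case mix, BCLC staging and treatment-allocation
    adherence accounting, propensity-score estimation with optimal 1:1
    matching and multiple imputation, Kaplan-Meier and parametric survival
    modelling with BIC-based family selection, a four-arm Markov cohort model
    accumulating discounted lifetime costs and life-years with transition
    calibration and ICER/dominance classification, and deterministic plus
    probabilistic (Monte Carlo) sensitivity analyses on the
    cost-effectiveness plane.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    survival,
    flexsurv,
    stats,
    utils,
    jsonlite,
    yaml,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
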