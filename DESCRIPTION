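Package: phenodose
Title: Population Pharmacokinetics and Dose Optimization of Phenobarbital
    in Refractory Status Epilepticus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Hierarchical one-compartment pharmacokinetic modelling of
    phenobarbital in critically ill adults with refractory and
    superrefractory status epilepticus. Implements allometric ideal-body-
    weight scaling of volume and clearance, lognormal interindividual and
    interoccasion variability, an exact piecewise-analytic concentration
    engine for mixed oral/intravenous dosing, Laplace/adaptive-quadrature
    nonlinear mixed-effects estimation with stepwise covariate selection
    and nonparametric bootstrap, Monte Carlo probability-of-target-
    attainment dose optimization for trough targets of 18-40 mg/L, and
    Bayesian maximum a posteriori individual dosing from therapeutic drug
    monitoring data. Includes a synthetic-cohort generator emulating an
    intensive-care trough-sampling design for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    pracma,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
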