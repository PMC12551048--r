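Package: mpapk
Title: Population Pharmacokinetics and Dosing Simulation for Mycophenolic Acid
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for population pharmacokinetic analysis of mycophenolic
    acid (MPA) in renal transplant recipients. Implements a closed-form
    one-compartment oral absorption model with multiple-dose superposition
    and steady-state exposure metrics; a population layer with lognormal
    inter-individual and inter-occasion variability, covariate effects on
    clearance, and additive/proportional/combined residual-error models;
    Laplace-approximation nonlinear mixed-effects estimation with stepwise
    covariate selection and predictive-check diagnostics (VPC/NPC); Monte
    Carlo simulation of dosing regimens under reduced clearance with
    dose-adjustment search against the 30-60 ug.h/mL AUC window; and a
    covariate-exploration stage based on principal components and
    gradient-boosted trees with Shapley attributions. A synthetic-cohort
    generator emulating a trough-only therapeutic drug monitoring design
    makes every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
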