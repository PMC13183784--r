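Package: harvestlab
Title: Individual-Based Simulation and Life-History Estimation for
    Size-Selective Harvest Experiments
Version: 0.1.0
Authors@R:
    person("Harvestlab", "Developers", email = "harvestlab@example.org",
           role = c("aut", "cre"))
Description: Simulates size-structured, iteroparous fish populations
    (modelled on experimental guppy lines) under positively
    size-dependent, negatively size-dependent and random harvest
    regimes, and provides the estimation toolkit used to analyse such
    selection experiments: logistic maturity ogives (L50) and
    probabilistic maturation reaction norms (Lp50), biphasic growth
    model fitting, weight-length allometry, directly observed and
    mark-recapture natural mortality estimators, life-table generation
    time, elasticity of traits to biomass, and phenotypic rates of
    change in haldanes. Includes an end-to-end pipeline reproducing the
    three-regime, multi-phase experimental design on synthetic data,
    with parameter-recovery validation throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
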