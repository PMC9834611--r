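Package: vblpbpk
Title: Physiologically Based Pharmacokinetic Modelling of Vinblastine
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A cross-species physiologically based pharmacokinetic (PBPK)
    simulator for the vinca alkaloid vinblastine. Implements a nine-compartment
    flow-limited model with saturable intracellular tubulin binding, ABCB1
    (P-glycoprotein) efflux in brain, gut, liver and kidney, a
    permeability-limited blood-brain barrier, and elimination by hepatic
    metabolism, biliary excretion and glomerular filtration. Ships parameter
    sets for wild-type and Mdr1a/b(-/-) knockout mice, dogs and humans, and
    provides noncompartmental analysis (linear-log trapezoidal AUC, terminal
    half-life), nonlinear least-squares parameter calibration with AIC/BIC
    model comparison, in vitro-in vivo extrapolation of microsomal
    Michaelis-Menten kinetics, Monte Carlo virtual populations with
    rank-correlated lognormal sampling, predictive-performance metrics
    (MAPE, MPE, RMSPE), and synthetic-data generators for testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
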