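Package: dualsis
Title: Dual-Channel Susceptible-Infected-Susceptible Market Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a two-channel susceptible-infected-susceptible (SIS)
    model of competing sales channels: logistic demand growth with signed
    cross-channel influence coupled to within- and cross-channel purchase
    transmission. Provides the single-channel, two-dimensional demand and
    four-dimensional demand-plus-purchase right-hand sides, closed-form and
    numerically bracketed equilibria with existence regimes, basic
    reproduction numbers and interior invasion thresholds, analytic Jacobians
    with eigenvalue stability classification cross-validated against the
    condition table, adaptive ODE simulation with convergence detection,
    phase-plane nullclines, saddle separatrix and basin partition, a seeded
    regime-stratified parameter sampler, and config-driven scenario sweeps
    with total-sales summaries and figures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    ggplot2,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
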