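Package: panicseir
Title: Delayed SEIR Evolutionary-Game Model of Panic Spread Under Emergencies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the spread of panic within a population during a
    major emergency as a one-way coupled system: an asymmetric two-population
    evolutionary game between an official opinion field (positive/negative
    guidance) and a public opinion field (positive/negative response), with
    replicator dynamics modified by within-group strategy-dependence
    coefficients, driving a delayed SEIR emotional-contagion model with
    Holling type II saturated incidence. Provides payoff and replicator
    right-hand sides, equilibrium finding and determinant/trace stability
    classification, the basic reproduction number and its sensitivity
    surfaces, infection-free and endemic equilibria with numeric spectral and
    Lyapunov-descent stability verification, a method-of-steps fourth-order
    Runge-Kutta integrator for the constant-lag system, scenario presets and
    report generation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
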