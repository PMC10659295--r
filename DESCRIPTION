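Package: vacfusion
Title: Satisficing Inference for a Guard-Cell Vacuole Fusion Signaling Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and likelihood-free inference for a dimensionless
    mass-action model of HOPS/trans-SNARE/Sec17 signaling in guard-cell
    vacuole fusion. Provides the stiff ODE model and its perturbation
    scenarios (PI3P depletion, fusion-trigger activation), rectified-linear
    satisficing criteria derived from qualitative vacuole-morphology
    phenotypes, quasi-random (Sobol' sequence) parameter-space screening,
    variance-based global sensitivity analysis with dummy-parameter and
    dummy-outcome controls, approximate Bayesian computation with sequential
    Monte Carlo (ABC-SMC) over the log-uniform prior box, and posterior
    interrogation (credible intervals, marginal and 2D histograms,
    steady-state composition surveys, replicate reproducibility tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    pracma,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
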