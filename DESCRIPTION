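Package: gomprad
Title: Two-Compartment Tumor Volume Kinetics and Single-Fraction Radiation Response
Version: 0.1.0
Authors@R: person("Maintainer", "Gomprad", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates tumor volume kinetics before and after a single high-dose
    radiation fraction using a two-compartment model: Gompertz-type growth in
    which the growth rate decays because tumor vasculature expands more slowly
    than the tumor (vascular growth retardation factor theta), and delayed
    radiation-induced cell death in which irradiated cells keep dividing for a
    few cell cycles during an active radiation-effect window before clearing.
    Division probability and kill rate derive from the linear-quadratic
    survival formalism. Includes a piecewise closed-form engine, an adaptive
    Runge-Kutta cross-check integrator, simulated-annealing least-squares
    parameter estimation, model scoring (mean squared relative difference and
    AIC), clinically oriented outcome metrics such as the 40-day volume ratio,
    ready-to-run parameter fixtures for rat rhabdomyosarcoma experiments and
    Gamma Knife stereotactic radiosurgery cases, a synthetic noisy-observation
    generator, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
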