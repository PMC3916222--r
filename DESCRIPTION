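Package: phoenixsim
Title: Kinetic Simulation of the Phoenix Rising PGE2-Secretion Pathway
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic kinetic model of the Phoenix Rising pathway, the
    signaling cascade by which apoptotic cells secrete prostaglandin E2 (PGE2)
    and stimulate proliferation of surrounding cells. Ten chemical species and
    seventeen reactions connect radiation-activated caspase-3/7 and NFkB to
    secreted PGE2 through iPLA2, arachidonic acid, COX2 and PGH2, using
    Michaelis-Menten, Hill and first-order rate laws with competitive product
    inhibition. Provides condition presets for MEF and 4T1 cells with and
    without 10-Gy irradiation, steady-state solvers (ODE relaxation and an
    independent algebraic cascade), the radiation time-course protocol,
    in-silico perturbation experiments (gene knockout, NFkB clamping, COX2
    inhibition, iPLA2 silencing, feedback removal, local sensitivity
    analysis), parameter-calibration routines, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
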