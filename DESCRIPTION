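Package: graftherm
Title: Thermal Feasibility Modelling of Infection-Sensing Vascular Grafts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulation toolkit for assessing heat-flux-sensor based detection
    of infections on aortic vascular grafts. Provides dimensionless-number and
    flow-regime calculators for pulsatile blood flow in the descending aorta,
    synthetic aortic pressure waveforms and their PDE forcing terms, a
    Crank-Nicolson solver for the oscillatory (Womersley) velocity component
    with a Bessel-function analytic oracle, a marching conjugate-heat solver
    that extracts the blood-side wall heat-transfer coefficient h(z) and its
    pulsatility dependence, biofilm thermal-power arithmetic, a 3D
    finite-volume conduction model of a sensor-bearing graft that converts
    infection heat sources into sensor-plane heat flux and detectability
    decisions, and a hexagonal sensor-array coverage design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
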