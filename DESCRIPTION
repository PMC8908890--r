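Package: gaitbalance
Title: Balance-Control Modeling of Human Walking with a COM-ZMP Inverted Pendulum
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modeling the balance controller of human walking with a
    center-of-mass / zero-moment-point (COM-ZMP) inverted pendulum. Provides the
    asymmetric-eigenvalue pendulum dynamics, a capture-point model-predictive ZMP
    stepping law with left/right switching for continuous walking, sensor-side ZMP
    estimation from foot-mounted force plates, rule-based detection of the seven
    Perry gait phases, identification of the controller parameters from COM/ZMP
    time series (in global or trunk-fixed local coordinates), a 15-segment
    anthropometric body model, and a closed-loop synthetic gait simulator that
    emulates 60 Hz motion-capture and force-plate recordings for testing without
    hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    signal
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
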