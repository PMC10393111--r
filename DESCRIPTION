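Package: cpbsim
Title: Simulation and Automatic Control of Cardiopulmonary Bypass Perfusion
Version: 0.1.0
Authors@R: person("CPB", "Simulation Team", role = c("aut", "cre"),
    email = "cpbsim@example.org")
Description: An in-silico testbed for automatic occluder control in
    cardiopulmonary bypass (CPB) circuits driven by a centrifugal pump.
    Provides a nonlinear static occluder-to-flow plant model with
    first-order-plus-dead-time actuation and a venous reservoir mass
    balance; nonlinear least-squares identification of the plant
    parameters from occluder-sweep and step-response data; a nested
    controller combining a two-degree-of-freedom model-matching arterial
    flow loop (static-model feedforward plus feedback PID) with an I-PD
    reservoir level loop; scenario runners reproducing perfusion
    (flow-up/flow-down) and venting/suction disturbance protocols; and
    mean-absolute-percentage-error metrics scoring flow tracking and
    level regulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
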