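Package: tado2i
Title: Temperature-Adjusted Indexed Oxygen Delivery Targets for
    Cardiopulmonary Bypass
Version: 0.1.0
Authors@R:
    person("tado2i", "Maintainers", email = "maintainers@tado2i.invalid",
           role = c("aut", "cre"))
Description: Computes temperature-adjusted critical indexed oxygen delivery
    (DO2i) targets for goal-directed perfusion during cardiopulmonary bypass.
    Implements three temperature-dependent models of the critical DO2i
    threshold (a Q10 exponential decay model, a Van't Hoff linear
    approximation, and a calibrated quadratic curve), body-surface-area
    scaling of per-square-metre targets, quadratic regression calibration
    with bootstrap confidence intervals, synthetic calibration-data
    generation, target trajectories over bypass temperature profiles, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
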