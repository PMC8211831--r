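Package: ventcal
Title: Indirect Calorimetry for Ventilated Subjects via the Direct Molar Ratio Method
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes oxygen consumption (VO2), carbon dioxide production
    (VCO2) and the respiratory quotient (RQ) of mechanically ventilated
    subjects from a directly measured molecular ratio of inhalation to
    exhalation (R = te/ti of a constant-rate gasbag pump), instead of the
    Haldane transformation, which is singular at FIO2 1.0. Includes the full
    sensor-correction chain (CO2/O2 cross-sensitivity, calibration-to-circuit
    pressure standardization, psychrometric humid-to-dry conversion, pre/post
    FIO2 drift interpolation), STPD volume standardization, first-order and
    Monte Carlo propagation of sensor errors through the VO2 equation, a
    mass-balance gas-exchange simulator with non-CO2-producing oxygen sinks
    for end-to-end parameter-recovery testing, exact Mann-Whitney U
    comparisons, and a command-line interface.
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
    withr
Config/testthat/edition: 3
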