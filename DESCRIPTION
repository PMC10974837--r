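Package: dhfsim
Title: Simulation and Uncertainty Analysis for Dual-Heat-Flux Core Body
    Temperature Probes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and analysing non-invasive dual-heat-flux
    (DHF) core body temperature (CBT) probes. Provides a steady-state lumped
    thermal model of the blood-skin-sensor-air stack that generates error-free
    sensor readings, six CBT estimator variants (heat-flux based and
    temperature-only, with paired-sensor and multi-equation averaging
    refinements), a Gaussian measurement-noise model for each variant's
    independent inputs, Monte Carlo propagation of measurement uncertainty
    with repeatability estimates, first-order Taylor uncertainty budgets with
    per-component shares, and parameter-sweep experiments over ambient
    temperature, core temperature, channel heat-transfer coefficients and
    convection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
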