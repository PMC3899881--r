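Package: spheroidO2
Title: Oxygen Reaction-Diffusion Modelling and Boundary Measurement for
    Tumour Spheroids
Version: 0.1.0
Authors@R:
    person("Spheroid", "Maintainers", email = "maintainers@spheroido2.org",
           role = c("aut", "cre"))
Description: Analytical steady-state oxygen transport model for avascular
    multicellular tumour spheroids. Computes radial oxygen partial-pressure
    profiles, the spherical diffusion limit, the anoxic-core radius and the
    asymptotic viable-rim limit from the spherical reaction-diffusion
    equation with constant (or Michaelis-Menten) consumption; inverts
    boundary measurements of stained spheroid sections to estimate the
    tissue oxygen-consumption rate; measures outer, anoxic and
    hypoxic/oxic-interface radii from multi-channel fluorescence section
    images by 360-ray radial boundary detection; generates ground-truthed
    synthetic dual-stained sections for validation; and provides an
    end-to-end analysis pipeline with consumption-drift and interface
    pressure sensitivity analyses, exposed both as R functions and as a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
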