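Package: ltdfit
Title: Bistable Synaptic-Efficacy Modelling of LTD Transients from Evoked
    Field Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for long-term depression (LTD) transients
    recorded as evoked local field potentials on multielectrode arrays.
    Extracts negative-peak amplitudes and ratio-index (RI) time courses with
    excitability and baseline-stability quality control, fits a modified
    bistable synaptic-efficacy differential equation to each six-point RI
    recovery curve by exhaustive grid search, classifies the fitted dynamics
    as monostable or bistable from the discriminant of the drift polynomial,
    and separates drug-condition groups by trajectory principal-component
    analysis, centroid distances and angles, a linear support-vector-machine
    boundary, and parameter-dispersion statistics. A deterministic synthetic
    data generator emulates seven pharmacological conditions at eight
    electrode sites so that every pipeline stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    e1071,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
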