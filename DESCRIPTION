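Package: silsub
Title: Silent Substitution Stimuli for Multiprimary Stimulation Devices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for designing photoreceptor-isolating light stimuli with the
    method of silent substitution. Builds photoreceptor action spectra for a
    parameterised colorimetric observer (age and field size, with lens and
    macular prereceptoral filtering), provides a forward model of a spectrally
    calibrated multiprimary stimulation device (calibration parsing, spectral
    prediction by interpolation, alpha-opic projection, gamma correction), and
    solves silent substitution problems - finding background and modulation
    spectra that modulate targeted photoreceptor classes while silencing
    others - by linear algebra and by constrained numerical optimisation
    (SLSQP). Includes synthetic fixture generators for devices and observers so
    the whole pipeline can be exercised without calibration hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    nloptr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
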