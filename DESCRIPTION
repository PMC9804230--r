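Package: thermspectrum
Title: Temperature-Dependent Multi-Species Size-Spectrum Food-Web Modelling
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulates a multi-species size-spectrum food web (three
    interacting fish species feeding on two background resource spectra)
    with Arrhenius temperature scaling of individual physiological rates
    (metabolism, maximum consumption, search volume, background mortality)
    and of resource regeneration and carrying capacity.  Provides an
    implicit upwind solver for the coupled McKendrick-von Foerster and
    semi-chemostat equations, Beverton-Holt recruitment, calibration of
    maximum recruitment to spawning-stock-biomass targets, FMSY search,
    warming projection ensembles over sampled activation energies, and
    synthetic generators for all external forcing inputs.
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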