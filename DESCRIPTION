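Package: ndvap
Title: Ultrasound-Assisted Carbon-Ion Dosimetry with Superheated Nanodroplets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis pipeline for particle-therapy dosimetry
    and range verification based on phase-change ultrasound contrast agents.
    Models the homogeneous-nucleation physics of superheated perfluorocarbon
    nanodroplet cores (degree of superheat, critical embryo radius, thermal
    spike linear-energy-transfer threshold), parametric carbon-ion depth-dose
    and LET curves (pristine and spread-out Bragg peaks), stochastic droplet
    vaporization in tissue-mimicking phantoms, synthetic B-mode grayscale
    imaging of the resulting microbubble fields, and the grayscale-profile
    quantification used for dose-response curves and sub-millimetre beam
    range verification.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    pracma,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
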