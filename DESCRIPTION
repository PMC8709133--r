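Package: npmicrodose
Title: Microdosimetry of Metallic-Nanoparticle Radiosensitization
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Microdosimetric analysis of radiosensitization by high atomic
    number nanoparticles (gold, gadolinium) under kilovoltage and megavoltage
    photon irradiation. Estimates proximity functions of energy-deposit point
    clouds from track structure, applies the generalized theory of dual
    radiation action with an exponential sublesion-combination distance model
    to obtain the linear-quadratic quality parameter, its nanoparticle-induced
    increase, the dose enhancement ratio and the relative biological
    effectiveness, and implements a phenomenological per-ionization
    cell-killing ("bomb") model that converts measured increases in the linear
    LQ coefficient into kill probabilities per nanoparticle ionization. A
    synthetic Auger-cascade track generator emulates the Monte Carlo
    track-structure output the pipeline consumes, so every stage is testable
    without a transport code.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
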