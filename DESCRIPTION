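Package: mimicolor
Title: Receptor-Noise Color Discrimination Analysis of Mimetic Wing Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for visual-ecology analysis of mimetic butterfly color
    signals. Implements quantum-catch computation from reflectance spectra
    with visual-pigment nomogram templates, receptor-noise-limited (RNL)
    chromatic and achromatic discrimination distances (just-noticeable
    differences, JND) for arbitrary receptor sets, calibrated-photography
    simulation with camera-to-cone-catch mapping, avian SWS1 opsin
    spectral-tuning classification (UVS vs VS), comimic-versus-conspecific
    JND statistics with a repeated-measures ANOVA, and a weighted binomial
    GLM for UV mate-choice trials. Includes seeded synthetic-data
    generators for wing-patch reflectance, comimic populations, camera
    training libraries, and mate-choice counts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
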