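Package: fluoql
Title: Estimating the Fraction of Open PSII Reaction Centers from Active and Passive Chlorophyll Fluorescence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Leaf-level analysis pipeline linking actively (PAM) and passively
    induced chlorophyll fluorescence to the fraction of open Photosystem II
    reaction centers (qL). Converts raw spectrometer digital numbers to
    radiance, derives lake-model quenching parameters (qL, NPQ) from PAM
    variables, corrects bidirectional fluorescence spectra for reabsorption,
    partitions photosystem-level emission into PSII and PSI components by
    non-negative decomposition, converts PSII spectral fluorescence to
    broadband photon flux (ChlF_PSII), and fits the ChlF_PSII-qL model with a
    peaked Arrhenius temperature dependence. Includes a synthetic response
    curve generator with known ground truth for end-to-end validation, and
    evaluation statistics grouped by plant functional type.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    readr,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
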