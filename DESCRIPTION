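Package: expanderRobust
Title: Robustness of Breast Radiotherapy to Tissue-Expander Port Motion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the dosimetric effect of inter-fractional positional
    variation of the metal injection port of a breast tissue expander during
    postmastectomy radiotherapy. Generates synthetic thorax/expander voxel
    phantoms, edits CT density grids (metal density overrides, artefact
    correction, rigid port shifts), computes dose with a simplified divergent
    photon-beam engine for tangential parallel-opposed, partial-arc and
    helical-like delivery, accumulates per-fraction dose under daily-variable
    and systematic internal-port and patient-registration errors, and reports
    DVH and point-dose-difference robustness metrics in a clinically
    meaningful peri-implant region of interest.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
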