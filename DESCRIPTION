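Package: hnokinetics
Title: Competition Kinetics of Azanone (HNO) with Cyclic C-Nucleophiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for determining second-order rate constants of azanone
    (HNO, nitroxyl) reactions with carbon-centred nucleophiles by boronate
    probe competition kinetics. Implements the full reaction-network ODE
    model of HNO release from Angeli's salt, its competing consumption by
    molecular oxygen, scavengers and dimerization, and peroxynitrite
    detection by a fluorescein-derived boronate probe; the quasi-steady-state
    closed forms and the (v0/vi - 1) inhibition law; a synthetic
    spectrophotometric trace generator with a Beer-Lambert optics and noise
    model; initial-rate and competition-slope estimators that recover the
    rate constants from absorbance traces; and a linear free-energy analysis
    relating computed activation barriers to the logarithm of measured rate
    constants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
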