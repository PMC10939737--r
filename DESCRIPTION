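Package: acxplast
Title: Auditory Cortex Adenosine, Tuning Plasticity and Perceptual Acuity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipelines for three read-outs of auditory-cortex
    neuromodulation experiments in mice: quantification of sound-evoked
    adenosine release from fast-scan cyclic voltammetry (background
    subtraction, oxidation-channel extraction, calibration, transient
    kinetics, pairing-epoch reduction and pseudo-Voigt delay-dependence
    fitting), two-photon calcium-imaging tuning analysis (dF/F, kinetics
    screened peak detection, stimulus assignment, tuning-frequency maps and
    pre/post plasticity shift statistics), and prepulse-inhibition based
    frequency-discrimination threshold scoring (psychometric logistic fits
    with exclusion rules). Seeded synthetic-data generators with recorded
    ground truth support parameter-recovery validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
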