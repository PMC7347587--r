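Package: uvckin
Title: Quantum-Kinetic Models of UV-C Induced Mortality in Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements two coupled models of UV-C germicidal inactivation of
    Escherichia coli: a physical model in which mortality grows with the
    logarithm of exposure time at a rate set by the cell quantum mortality
    yield, and a corpuscular (photon-base collision) model built from the
    effective impact cross-section, mean free path, excitation time and
    lethal impact number of the genome matrix. Provides closed-form
    theoretical predictions for the specific speed of mortality, minimum
    mortality time and quantum mortality yield; least-squares estimation of
    these parameters from colony-forming-unit survival data with confidence
    and prediction bands and a one-mean t-test against theory; the
    proportionality-hypothesis (photons-per-dimer) accounting; and a seeded
    simulator of serial-dilution plate-count experiments for parameter
    recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
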