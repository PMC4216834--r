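Package: thalcort
Title: Thalamo-Cortical Phase-Oscillator Model of Stimulus Phase Locking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of a thalamo-cortical loop built from
    mean-field-coupled populations of nonidentical Kuramoto-type phase
    oscillators with Lorentzian frequency distributions. Provides the full
    N-oscillator model (two or three populations), its Ott-Antonsen
    low-dimensional reduction, stimulus-locking-index metrics, bifurcation
    analysis of the reduced system (Hopf and fold-limit-cycle loci, region
    classification), coupling-plane scans, and calibration of coupling
    strengths to target synchronization levels such as those reported for
    healthy controls and schizophrenia patients in auditory EEG studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    pracma,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
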