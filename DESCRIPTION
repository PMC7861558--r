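Package: polswitch
Title: Mechanisms of Signal-Induced Cell Polarity Switching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Deterministic and stochastic simulation of a three-compartment
    (two poles plus cytoplasm) cell-polarity circuit of a polarity marker,
    its antagonist and a recruitment factor, driven by a transient signaling
    protein pulse. Provides the three-phase switching protocol, systematic
    scans of all 22 single-rate regulation scenarios over signal amplitude
    and duration, classification of persistent-signal dynamics into
    polarized, oscillatory and symmetric regimes, assignment of successful
    switches to one of four mechanisms (transient oscillator, reset,
    prime-release, push), fixed-point and separatrix estimation, limit-cycle
    extraction, and Welch power spectra with a coherence-resonance metric.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    MASS,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
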