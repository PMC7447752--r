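Package: memfir
Title: Memristor-Crossbar Simulation of FIR Filtering and Perceptron
    Decoding for Neural Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Software simulator for an analog neural-signal analysis system
    built on memristor crossbar arrays. Implements a four-band (delta, theta,
    alpha, beta) linear-phase FIR filter bank mapped onto differential
    conductance pairs, a single-layer perceptron decoder for epileptic-state
    classification (normal, interictal, ictal), configurable device
    non-idealities (programming error, read noise, conductance bounds), a
    synthetic local-field-potential generator for end-to-end testing, and an
    itemized power-efficiency model comparing the analog crossbar system with
    a CMOS baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
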