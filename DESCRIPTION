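Package: xrfret
Title: Single-Molecule FRET Folding Kinetics and Xrn1 Decay Analysis for
    Exoribonuclease-Resistant RNAs
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the magnesium-dependent folding of
    exoribonuclease-resistant RNA elements (xrRNAs) by single-molecule FRET
    and fluorescence-based Xrn1 decay assays. Provides a continuous-time
    Markov chain simulator for three-state conformational dynamics with
    realistic camera emission models, TIRF spot detection and dual-channel
    registration, hidden Markov model trace idealization (Baum-Welch and
    Viterbi), dwell-time and transition-rate estimation, transition density
    plots, free-energy landscape reconstruction, Hill analysis of titration
    curves, normalized exonuclease decay-rate fitting, and Guinier and
    dimensionless-Kratky SAXS metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    minpack.lm,
    mclust,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    tiff,
    bio3d,
    knitr
LinkingTo: Rcpp
Config/testthat/edition: 3
RoxygenNote: 7.3.3
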