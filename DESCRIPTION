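Package: mupop
Title: Motor Unit Population Analysis from Multichannel Intramuscular EMG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for simulating and analysing populations of motor
    neurons recorded with high-density intramuscular electrode arrays.
    Includes an integrate-and-fire motor-neuron pool driven by common
    sinusoidal input, synthesis of multichannel EMG as a convolutive
    mixture of motor-unit action potentials, blind source separation of
    the EMG into motor-unit discharge patterns by convolution kernel
    compensation with pulse-to-noise-ratio gating, agreement metrics
    between discharge patterns (rate of agreement, sensitivity,
    precision), pooled coherence of cumulative spike trains with an
    analytic confidence level, and directional pooled cross-histograms
    with surrogate controls and a Kolmogorov-Smirnov dip comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
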