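Package: lecensemble
Title: Phasic and Tonic Ensemble Coding Analysis for Blocked Trace Eyeblink Conditioning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multi-block trace eyeblink conditioning
    electrophysiology sessions: conditioned-response scoring from eyelid EMG
    (Hilbert envelope with threshold rules), single-unit CS-responsiveness and
    differential-index selectivity with permutation shuffle correction,
    Kullback-Leibler firing-rate stability, ensemble state-vector correlation
    analyses across trial blocks, and pseudo-population SVM decoding of block
    identity. Includes a synthetic-session generator (piecewise-homogeneous
    Poisson spiking with configurable phasic/tonic selectivity, and EMG with
    conditioned-response bursts) so every stage can be validated against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
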