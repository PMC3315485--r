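Package: bindspec
Title: Information-Theoretic and Thermodynamic Analysis of
    Transcription-Factor Binding Specificity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse the binding specificity of DNA-binding
    proteins from measured relative association constants and from pooled
    selection chromatograms. Builds per-position frequency and binding
    free-energy matrices, converts energies to frequencies by Boltzmann
    weighting, computes sequence-logo information content (Rsequence) with
    exact small-sample correction, scores sites by individual information
    (Ri), compares motif models by symmetrised Kullback-Leibler
    divergence, estimates the non-specific binding energy from paired
    regressions of binding energy on Ri, quantifies cross-variant site
    overlap and expression-affinity correlation, and includes a seeded
    synthetic-data generator (additive energy truth, two-state
    non-specific floor, log-normal measurement noise, Boltzmann selection)
    so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings,
    jsonlite
Config/testthat/edition: 3
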