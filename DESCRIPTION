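Package: megfusion
Title: Time-Resolved MEG Decoding, Representational Similarity Fusion, and
    Nonparametric Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of time-resolved multivariate pattern
    analysis (MVPA) for magnetoencephalography (MEG) and its fusion with
    functional MRI by representational similarity analysis (RSA). Provides a
    synthetic-data generator with known ground-truth representational
    structure; epoch preprocessing (baseline correction, peak-to-peak
    rejection, zero-phase low-pass filtering); pairwise support-vector-machine
    decoding into time-resolved representational dissimilarity matrices,
    categorical-division statistics and temporal generalization maps;
    correlation-based fMRI RDMs (region-of-interest and searchlight),
    MEG-fMRI fusion by Spearman rank correlation, and metric multidimensional
    scaling; plus the accompanying nonparametric inference layer (d-prime,
    signed-rank tests, bootstrap peak/onset latencies with confidence
    intervals, false-discovery-rate correction, and sign-permutation
    cluster-size inference). A pipeline orchestrator runs the full chain from
    a single seeded configuration with provenance tracking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
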