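Package: ictonet
Title: Directed EEG Functional Connectivity and Brain Network Ictogenicity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers directed functional connectivity networks from
    multichannel background EEG using surrogate-corrected lagged
    cross-correlation, quantifies network asymmetry with node-level and
    global graph measures, and estimates each node's contribution to
    epileptiform dynamics with a theta-neuron model and virtual node
    resection (brain network ictogenicity, BNI, and node ictogenicity,
    NI). Includes a synthetic multichannel EEG generator with planted
    directed lag structure, stage-dependent hemispheric symmetry
    breaking, and annotated events, plus nonparametric group statistics
    (rank tests, Benjamini-Hochberg FDR, AUROC effect sizes) and an
    end-to-end reproducible pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
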