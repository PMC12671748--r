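Package: CalciumEnsembles
Title: Ensemble, Behavior-Relevance and Functional-Network Analysis of
    Miniscope Calcium Imaging
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing extracted single-neuron calcium traces
    recorded at 10 Hz during social-interaction and object-exploration
    sessions: z-score normalisation and binary behavior-vector
    construction, neuronal-ensemble detection by k-means clustering with
    within-cluster-sum-of-squares model selection, classification of
    behavior-relevant neurons against a circular-shift permutation null of
    the cosine similarity, functional-network inference from
    phase-randomisation surrogates with degree-centrality summaries, a
    seeded generator of GCaMP-like synthetic sessions with ground-truth
    neuron classes and cross-session identity, and chow-equivalent
    nutrient-intake arithmetic for dietary supplement cocktails.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    withr,
    igraph,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
biocViews: Software, Clustering, Network, SingleCell
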