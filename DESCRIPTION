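Package: anchornet
Title: Anchor-Gene Expression, Survival, Drug-Connectivity and Causal Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking a single anchor gene to a downstream
    transcription-factor signaling program in multi-cohort expression data:
    differential-expression meta-analysis by summed -log10 p-values,
    median-split survival stratification with Kaplan-Meier, log-rank and Cox
    proportional-hazards models, a weighted Kolmogorov-Smirnov drug
    connectivity score for querying perturbation compendia with up/down gene
    signatures, constrained score-based Bayesian-network structure learning by
    multi-chain MCMC with consensus averaging and deterministic cycle removal,
    shortest-path subnetwork extraction, layer-wise downstream-neighborhood
    enrichment and key-driver analysis. A seeded synthetic-data module
    generates every input the pipeline consumes from a linear-Gaussian
    structural equation model on a ground-truth DAG, so the full analysis is
    testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    igraph,
    jsonlite,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
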