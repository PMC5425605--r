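Package: dynfc
Title: Dynamic Functional Connectivity and Modular Network Organization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Sliding-window dynamic functional connectivity analysis for
    node-level resting-state time series: Fisher-z connectivity matrices,
    resolution-tuned Louvain community detection with agreement-matrix
    consensus, per-window modularity and between-network connectivity,
    within-subject cross-level correlations between bi-nodal (amygdala-mPFC)
    connectivity and large-scale network organization, and within-subject
    linear support vector regression over network-network interactions.
    Includes a synthetic cohort generator with planted coupling dynamics and
    trauma-severity effects so that every stage of the analysis can be
    validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    e1071,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
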