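Package: subconn
Title: Subcortical Structural Connectome Statistics and Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Group analysis of subcortical structural connectomes built from
    probabilistic-tractography streamline counts. Provides connectome assembly
    and filtering for an 18-region subcortical atlas, threshold-free
    network-based statistics (TFCE-style enhancement of edge-wise F statistics
    over graph components) with permutation inference and false discovery rate
    control, pairwise post-hoc contrasts, nested leave-one-out classification
    with recursive feature elimination and a linear support vector machine,
    and a synthetic cohort generator parameterized from published group
    summary statistics for healthy controls, Parkinson's disease and multiple
    system atrophy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    e1071,
    igraph,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
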