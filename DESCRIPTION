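Package: graphme
Title: Personalized Structural Connectome Profiling Against Normative Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-subject profiling of weighted structural brain connectomes.
    Computes an eight-metric global graph profile (strength, characteristic path
    length, global efficiency, greedy geometric navigation efficiency, local
    efficiency, clustering coefficient, clustering normalized to
    degree-preserving rewired surrogates, and betweenness centrality) for one
    patient, compares it against a healthy-control reference cohort as a radar
    ('GraphMe') profile with 95% interval categorization, and localizes
    alterations through betweenness hubs and edgewise/nodewise z-score deviation
    maps with Benjamini-Hochberg false discovery rate control. Includes a
    synthetic-cohort generator with injectable lesions for validation with
    known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
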