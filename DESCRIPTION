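Package: dicenet
Title: Differential Centrality-Ensemble Analysis of Condition-Specific
    Interaction Networks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Prioritizes condition-associated genes by combining relaxed
    differential expression, information-gain feature filtering,
    condition-specific correlation-weighted protein-protein interaction
    networks, differential betweenness and eigenvector centrality, and
    ensemble rank aggregation. No seed or disease gene lists are required.
    Includes a synthetic two-condition expression simulator with planted
    differential expression and differential co-expression for validation,
    and a hypergeometric over-representation step for annotating the
    resulting gene sets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    MASS,
    Rcpp,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Network, GeneExpression, DifferentialExpression,
    NetworkInference, GraphAndNetwork
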