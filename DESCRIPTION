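Package: rhizonet
Title: Co-Occurrence Network Analysis of Root Microbiome OTU Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers microbial co-occurrence networks from OTU count tables
    using the maximal information coefficient (MIC) with permutation
    significance and Benjamini-Hochberg false discovery rate control,
    identifies keystone taxa by joint degree, closeness and betweenness
    centrality criteria, compares networks across management groups
    (bootstrap and Kolmogorov-Smirnov tests, per-farm subgraph
    connectivity versus agricultural intensity), attributes keystone
    abundance to soil covariates by random-forest permutation importance,
    and supplies alpha/beta diversity and indicator species analysis.
    Includes a synthetic study generator with planted hub taxa and known
    ground truth for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    igraph,
    jsonlite,
    randomForest,
    Rcpp,
    stats,
    utils,
    vegan
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
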