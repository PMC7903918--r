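Package: corenet
Title: Causal Regulatory Network Prediction from Signed Interaction Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds signed gene-regulation graphs from curated interaction
    tables and microRNA seed-match evidence, propagates misregulation signs
    upstream from differentially expressed genes to a perturbed root
    regulator, prunes sign-inconsistent links and extracts shortest-path
    causal subnetworks for export in simple interaction format. Also
    provides seed-complement scanning of 3'UTR sequences with between-strain
    comparison, hypergeometric heptamer enrichment landscapes over ranked
    gene lists, degree and betweenness centrality reports, closed-form
    two-group power and Mendelian genotype-ratio statistics, and seeded
    synthetic-data generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    igraph,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
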