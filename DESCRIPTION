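Package: bacmine
Title: Bacteriocin Mining and Strain-Diversity Association in Gut Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Desk-scale pipeline for mining bacteriocin genes from gut
    metagenomes and relating their presence to within-species strain
    diversity. Provides a six-frame translated protein search with
    Karlin-Altschul E-values, per-sample bacteriocin gene abundance,
    age-group enrichment testing with false discovery rate control and
    prevalence tiering, bacteriocin clustering by normalized alignment
    bit score, genome-collection screening into per-taxon profiles, a
    k-mer read-to-genome classifier with community profiling, rarefied
    genome-count strain-diversity analysis fit with an analysis of
    covariance model, and a contig operon scan. A synthetic-data
    generator with full ground truth makes every stage testable without
    external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    vegan,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
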