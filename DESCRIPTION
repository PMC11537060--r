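Package: spongenet
Title: Co-Occurrence Network and Diversity Analysis of Sponge Holobiont Microbiomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Community-ecology workflow for host-associated (sponge) and
    seawater 16S ASV tables: partitioning of taxa into abundant, dominant and
    rare classes by relative-abundance thresholds; alpha diversity, Bray-Curtis
    dissimilarity, hierarchical clustering, and permutation tests (ANOSIM,
    PERMANOVA, MRPP, Mantel) with variance-inflation screening of environmental
    variables; Levins niche breadth; correlation-based molecular ecological
    networks with a random-matrix-theory threshold, Maslov-Sneppen null
    ensembles and keystone ranking; local similarity analysis of time series
    for bipartite host-seawater association networks; and a synthetic
    community generator emulating high- and low-microbial-abundance sponge
    phenotypes so the entire pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vegan,
    igraph,
    ape,
    jsonlite,
    biomformat,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
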