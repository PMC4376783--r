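Package: threewaynet
Title: Weighted Three-Way Similarity Networks from Gene-Family Content
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds weighted 3-uniform hypergraphs ("3-way networks") over
    bacterial species from gene-family count profiles, alongside classical
    pairwise networks. Implements the 2-way and 3-way Sorensen and
    Czekanowski similarity indices, theorem-justified threshold pruning
    (any threshold above 0.75 retains only triplets with a non-empty
    three-way intersection), best-x-edge and maximum-spanning-tree pruning,
    combined 2-way/3-way networks, gene-family enrichment networks via
    Fisher's exact test with Holm-Bonferroni correction, a rank-based
    disagreement measure between pairwise and triplet topologies, and
    edge-node expansion for visualisation in standard graph viewers.
    Includes a synthetic gene-family matrix generator with genus block
    structure for end-to-end testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    igraph,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
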