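Package: bridgenet
Title: Bridgeness and Community Topology Analysis of Protein Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds bait-interactome protein-protein interaction networks from
    curated edge tables filtered to direct and physical interactions, detects
    communities with several published algorithms, derives bootstrap-based soft
    community memberships and a consensus partition, and classifies proteins
    into influence regions by combining semi-local centrality with consensus
    bridgeness. Includes hypergeometric annotation enrichment per community
    with a permutation strength-of-significance test, the disease-module
    separation statistic S_AB with a randomized null model, cross-interactome
    overlap tests, and seeded planted-partition generators so the whole
    pipeline is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
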