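Package: linkEntropy
Title: Link Entropy Edge Significance and Percolation-Based Network Robustness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the significance of network edges for maintaining
    global connectivity with the Link Entropy (LE) score: a symmetric
    nonnegative matrix factorization of the self-looped adjacency matrix
    yields a row-stochastic community-membership distribution per node, and
    each edge is scored by combining the Shannon entropy of its endpoints'
    membership distributions with the Jensen-Shannon divergence between
    them. Six benchmark edge-importance indices (edge betweenness, degree
    product, bridgeness, diffusion importance, topological overlap and
    ERW-Kpath centrality) and a targeted edge-attack percolation harness
    (giant-component fraction, normalized susceptibility, percolation
    threshold detection, replication studies) are included for comparison,
    together with seeded synthetic network generators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
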