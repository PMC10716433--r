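Package: netrestore
Title: Collapse and Restoration Dynamics for Mutualistic Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates species-loss perturbations, obligate-mutualism
    extinction cascades, and network-guided species reintroduction in
    bipartite plant-pollinator networks. Provides the full (n-dimensional)
    mutualistic community model with Holling type II saturation, its
    two-dimensional (effective plant/pollinator) and one-dimensional
    (projected, beta_eff-controlled) reductions, topology metrics (NODF
    nestedness, connectance, asymmetry, degree/closeness/betweenness
    centrality, one-mode projection), a synthetic bipartite network
    generator with controllable connectance and degree heterogeneity,
    restoration-strategy ranking and exhaustive pathway enumeration, and
    an ensemble experiment driver with winner identification and
    attribute-criterion statistics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    vegan,
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
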