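Package: cvxndl
Title: Online Convex Network Dictionary Learning for Multiway Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Learns small, interpretable dictionaries of subnetwork patterns
    from large interaction networks, with a focus on multiway chromatin
    contact data. Hyperedge lists (e.g. droplet-based multiway chromatin
    contacts over genomic bins) are clique-expanded into an undirected
    network; k-node path subnetworks ("patches") are drawn with a
    Markov-chain Monte Carlo pivot sampler; and dictionary elements are fit
    online under a convexity constraint, so that every element is a simplex-
    weighted combination of real sampled subnetworks and can be mapped back
    to genomic coordinates. Includes an unconstrained online network
    dictionary learning baseline, network reconstruction from a dictionary
    with average-precision evaluation, and synthetic stochastic block model
    and planted-motif generators for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    methods,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
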