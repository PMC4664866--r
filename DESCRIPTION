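Package: cblink
Title: Community-Based Link Prediction and Network Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts missing links in undirected networks with community
    structure and reconstructs networks that preserve global topology.
    Local similarity scores (common neighbours, resource allocation) are
    combined with a modularity-maximising partition: intra- and
    inter-community candidate lists are ranked separately and merged by a
    tunable interleaving probability beta. Beta can be learned by threefold
    validation so that the mean edge betweenness of the predicted links
    matches that of held-out links, optionally constrained to bound the loss
    of ranking accuracy (AUC). Includes an extremal-optimisation community
    detector, a planted four-community benchmark generator, exhaustive AUC
    and precision evaluation, and a reconstruction protocol that compares
    structural and dynamical indices (shortest path, clustering,
    assortativity, congestibility, synchronizability, epidemic spreading
    ability) between reconstructed and original networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Matrix,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
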