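Package: sourceloc
Title: Multi-Source Localization in Complex Networks from Sparse Observers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Locates multiple propagation sources in an undirected contact
    network from the informed times of a sparse set of observer nodes,
    without knowledge of the propagation dynamics or their parameters.
    Candidate nodes are scored by the sum of prefix Pearson correlations
    between their sorted observer distances and the corresponding observer
    informed times; rankings are evaluated by tie-aware ROC AUC against the
    true source set. Includes seeded Erdos-Renyi and Barabasi-Albert
    generators, degree-preserving rewiring, Gaussian-delay diffusion and
    discrete-time susceptible-informed (SI) simulators, a locatability
    analysis of observer sets (affine distinguishability of distance
    vectors), and a greedy observer-selection strategy that maximizes the
    number of distinguishable node pairs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
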