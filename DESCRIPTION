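Package: axoclass
Title: Statistical Classification of Brain-Wide Axonal Projection Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies statistically distinct projection-neuron classes from
    brain-wide single-axon reconstructions. Neurons are represented as vectors
    of axonal point counts per brain parcel; a marginal-preserving swap
    randomization generates the single-class null; pairwise arccosine
    projection distances are compared with a one-tailed Levene variance test
    that gates recursive average-linkage hierarchical clustering. Downstream
    quantifications include non-negative least-squares estimation of class
    population fractions from regional anterograde tracing profiles,
    convex-hull analysis of soma topography, along-tree path-distance
    divergence and convergence statistics, and Strahler-order branch metrics
    justifying point counts as the measure of axonal extent. Includes seeded
    synthetic-data generators, SWC and MouseLight-style JSON readers, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    pracma,
    ape
Suggests:
    testthat (>= 3.0.0),
    igraph,
    car,
    optparse
Config/testthat/edition: 3
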