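Package: riccinet
Title: Ricci Curvature and Normalised Ricci Flow for Expression-Weighted
    Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the rewiring of protein-interaction networks
    weighted by gene-expression profiles under the mass-action principle.
    Computes random-walk network entropy (local entropies, entropy rate and
    its topology-normalised form), a degree-normalised Forman-Ricci curvature
    on edges with nodal and stationary-weighted totals, and a normalised
    discrete Ricci flow that interpolates edge distances between two
    transcriptomic states. Includes closed-form entropy and curvature for the
    k-star toy network with regime scans, trajectory evaluation of inferred
    rewiring paths against intermediate samples (closest-pass ordering,
    Pearson and Fisher-z statistics), and synthetic-data generators for stars,
    random sparse interactomes and time courses.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
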