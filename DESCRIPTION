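Package: antagonet
Title: Analysis of Microbial Antagonism Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for building and analysing directed networks of
    antibiotic-mediated inhibition among sympatric bacterial isolates,
    as assayed by agar-overlay inhibition zones. Raw replicated zone
    measurements are binarized into directed interaction networks, which
    are characterised by density, degree distributions, mean directed
    shortest path length, directed transitivity and small-world indices,
    and compared against three null-model ensembles (Erdos-Renyi,
    dyad-conditioned and degree-preserving edge rewiring). A census of
    the sixteen directed triad isomorphism classes supports motif
    detection with z-tests and false-discovery-rate control, chi-squared
    goodness-of-fit tests with Monte-Carlo p-values, and cross-community
    comparisons. Node participation in the thirty positions (orbits) of
    connected triads yields per-isolate signature vectors for
    correlation-based hierarchical clustering and Shannon diversity
    analysis. A seedable synthetic-community generator emulating
    'super-killer' dominated out-degree distributions makes every stage
    testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    igraph,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
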