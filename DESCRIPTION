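Package: ladsim
Title: Coarse-Grained Simulation of Chromatin-Lamina Organization in the Nucleus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Brownian dynamics of a coarse-grained chromatin chain (a
    self-attracting bead-spring polymer, one bead per ~600 bp) confined to a
    spherical nucleus lined with a static shell of lamin beads.
    Lamina-associated domains (LADs) form and break explicit bonds with the
    lamina, with the bondable fraction, chromatin volume fraction and
    self-attraction strength as control parameters.  Includes builders for
    bead-type patterns from BED-like LAD annotations or a synthetic block
    generator, an overdamped Langevin integrator with cell-list neighbour
    search (compiled core), a two-stage equilibration protocol, and analysis
    of radial volume-fraction profiles, organization-mode classification
    (peripheral, conventional, central), contact maps and P(s), subchain
    scaling exponents, persistence length, and angular LAD segregation, plus
    a parameter-sweep driver for state diagrams.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    IRanges,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
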