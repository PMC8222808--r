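Package: macboolnet
Title: Synchronous Boolean Network Analysis of Macrophage Polarization
Version: 0.9.0
Authors@R: person("Human Systems", "Maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A synchronous Boolean network toolkit built around a curated model of
    macrophage polarization in a tumor microenvironment. Parses rule files in the
    "targets, factors" dialect, enumerates attractors and basins exhaustively over
    the full state space with a bit-parallel C++ engine, labels attractors with
    M1/M2a/M2b/M2c/M2d phenotype marker logic, runs knockout/overexpression and
    microenvironment perturbation scans with log2 basin fold-changes, builds
    single-bit-flip cell-fate maps with reversibility classification, constructs
    theoretical genetically modified macrophages (TGEM/STGEM) and simplified breast
    cancer scenarios, and quantifies robustness with Derrida curves and per-rule
    sensitivity analysis. Includes generators of random Boolean networks and fixture
    networks with analytically known landscapes for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
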