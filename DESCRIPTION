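Package: aquabridge
Title: Geometric Placement of Bridging Water Molecules in Protein Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts explicit bridging water molecules between pairs of polar
    sites (side-chain rotamers, backbone atoms and ligand atoms) by a purely
    geometric construction: for every eligible polar-atom pair, the locus of
    ideal hydrogen-bond distances is a circle between the two atoms, and the
    water oxygen is placed at the perimeter point closest to the mutual
    orientation of the donor/acceptor direction vectors. Includes a directional
    hydrogen-bond energy gate, a simplified side-chain packing engine
    (dead-end elimination plus Monte-Carlo simulated annealing) that carries
    solvated rotamers, crystallographic-symmetry-aware sphere extraction,
    water-geometry statistics, and a full validation metric suite
    (unique-match mesh scoring, recovery curves, chi-1 recovery, side-chain
    RMSD) together with deterministic synthetic fixtures with analytically
    known water positions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    tibble,
    purrr,
    rlang,
    MASS,
    stats,
    utils,
    ggplot2,
    generics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
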