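Package: alphadimer
Title: Weighted Alpha-Shape Descriptors of Protein Dimer Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Geometric characterization of protein-protein dimer interfaces
    over structure trajectories. Builds weighted alpha complexes (regular
    triangulations of heavy atoms filtered at alpha = 0, with atomic weights
    equal to squared van der Waals radii), extracts interfacial atom sets by
    comparing monomer and dimer surfaces, scores convex/concave shape
    complementarity of cross-chain atom pairs through atomic solid angles,
    and reports per-frame matching rates and mean center-of-mass distances
    as moving-average-smoothed trajectory series. Includes a synthetic
    structure generator (lattice blocks, slab dimers, knob-hole dimers,
    rigid-body separation trajectories) with known ground truth, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
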