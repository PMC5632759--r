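Package: pMHCsurf
Title: Electrostatic Similarity of Peptide-MHC TCR-Interacting Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structure-based estimation of the intrinsic likelihood of T-cell
    cross-reactivity among peptide-MHC (pMHC) complexes. Reads and canonically
    orients 3D structures, computes electrostatic potentials over the
    TCR-interacting surface (screened Coulomb or finite-difference linearized
    Poisson-Boltzmann), rasterizes the surface in a fixed orientation, extracts
    region-based image descriptors, and clusters complexes by correlation
    distance with average linkage, attaching multiscale-bootstrap approximately
    unbiased (AU) and bootstrap probability (BP) support values with standard
    errors. Includes utilities to compare structure-derived partitions against
    observed cross-reactivity networks and a deterministic toy-groove generator
    for fully synthetic ground-truth benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    bio3d,
    ape,
    jsonlite,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    Biostrings,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
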