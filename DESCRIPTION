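Package: fragdecomp
Title: Fragment-Based Interaction-Energy Decomposition for Protein-Ligand Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Per-residue decomposition of protein-ligand interaction energies by
    the molecular fractionation with conjugate caps (MFCC) scheme, with pluggable
    energy backends and an exact classical pairwise potential for verification.
    Includes trajectory descriptors (RMSD, delta-RMSD, per-residue RMSF with
    Kabsch superposition), geometric hydrogen-bond detection with trajectory
    occupancy and water bridges, conformational-ensemble clustering (dimensionality
    reduction plus Gaussian mixtures) with representative-conformation extraction,
    binding-site radius-convergence profiles, per-residue interaction panels,
    docking-pose classification, and synthetic protein-ligand complex generators
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    bio3d,
    mclust,
    igraph,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
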