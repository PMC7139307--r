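Package: fibrilstab
Title: Stability Metrics and Receptor Selection for Cross-Beta Amyloid
    Fibril Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trajectory analysis for stacked cross-beta amyloid fibrils
    such as the S-shaped Abeta42 polymorph. Reads multi-model PDB
    trajectories, assigns beta structure with the Kabsch-Sander
    hydrogen-bond model, computes a chain-orientation order parameter,
    inter-chain interaction (buried) surface areas via Shrake-Rupley
    quadrature, per-residue ligand contact probabilities with
    bound-frame masking, and selects docking receptors as centroids of
    single-linkage RMSD clusters. Includes a deterministic generator of
    idealized cross-beta pentamer structures and distorted trajectories
    for validation and demonstration without a molecular dynamics
    engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
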