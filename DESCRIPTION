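Package: pocketgrid
Title: Voxel-Based Prediction and Evaluation of Protein-Ligand Binding Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for grid-based protein-ligand binding-site prediction:
    reading and writing TRIPOS mol2 and PDB structures, 18-channel atomic
    featurization, voxelization of proteins and binding sites onto a fixed
    36x36x36 grid, a structural-similarity data-cleaning pipeline built on
    k-mer MACCS fingerprints and sliding-window Tanimoto similarity, a
    residual U-Net builder for volumetric segmentation with exact layer and
    parameter accounting, dice-loss training on synthetic fixtures, pocket
    extraction from probability grids, and the DCC/DVO/PLI/F1 evaluation
    suite. A deterministic fixture generator produces toy proteins, sites,
    and probability grids so the whole pipeline is testable without any
    external dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    igraph,
    jsonlite,
    yaml,
    generics,
    bio3d,
    ChemmineOB,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
SystemRequirements: Open Babel (obabel) for Gasteiger charges and atom
    typing in featurization.
Config/testthat/edition: 3
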