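Package: voxmut
Title: Structure-Guided Missense Variant Pathogenicity Prediction with 3D Convolutional Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encodes the three-dimensional structural microenvironment of a
    missense variant as a multi-channel voxel grid and classifies the variant
    as benign or pathogenic with a 3D convolutional neural network. Provides
    PDB structure ingestion with eligibility filtering, per-atom
    physicochemical and conservation feature calculation (atomic densities,
    charges, Coulomb and Lennard-Jones pair potentials, Shrake-Rupley solvent
    accessibility, position-specific scoring matrix profiles), Gaussian
    mapping of atom-localized features onto voxel grids with rotational data
    augmentation, protein-level cross-validation and balanced training with an
    AdamW optimizer, and an evaluation suite (Matthews correlation
    coefficient, ROC/AUC, relative-accessibility burial analysis, odds
    ratios, inheritance-stratified metrics, feature ablation). A synthetic
    data generator produces small helical-bundle structures, conservation
    profiles and labeled variant tables with a planted buried-and-conserved
    pathogenic signal so the full pipeline can be exercised at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    tibble,
    tidyr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
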