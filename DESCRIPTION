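Package: nethom
Title: Network Homogeneity Analysis of Resting-State fMRI Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Voxel-wise network homogeneity (NH) analysis of resting-state
    fMRI data within a network mask, as used in case-control studies of the
    default-mode network. Provides a seeded synthetic BOLD cohort generator
    with planted coupling effects, temporal preprocessing with framewise
    displacement motion QC, group-ICA derivation of a binary network mask,
    fast per-voxel NH computation with a brute-force oracle, covariate
    adjusted voxel-wise group inference with permutation cluster-extent
    family-wise error correction, Pearson correlation of region-mean NH with
    clinical variables, and single-region support vector machine
    classification with leave-one-out cross-validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    e1071,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
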