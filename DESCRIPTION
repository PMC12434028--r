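Package: striatparc
Title: Connectivity-Based Striatal Compartment Parcellation on Synthetic Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Probabilistic-tractography parcellation of the striatum into
    matrix-like and striosome-like compartments, exercised end-to-end on
    synthetic striatum phantoms with known compartment ground truth. Provides
    a phantom generator emulating histological compartment organization
    (15:85 striosome:matrix abundance, tubular separated striosomes,
    rostro-ventral striosome location bias, somatotopically segregated bait
    connectivity), a simplified probabilistic streamline tracker
    (classification-targets and streamline modes with waypoint/avoid masks),
    compartment classification with high-bias equal-volume masks, N-1
    leave-one-bait-out somatotopic zone mapping, and group-level inference:
    covariate-adjusted ANOVAs with Benjamini-Hochberg correction and
    voxelwise permutation testing with variance smoothing and threshold-free
    cluster enhancement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
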