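Package: bmchex
Title: Geometry and Energetics of Bacterial Microcompartment Shell Hexamer Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how bacterial microcompartment shell hexamers
    (BMC-H) tile into two-dimensional layers and bend out of them. Reconstructs
    hexamer layers from crystallographic symmetry, classifies inter-hexamer
    arrangements (Arr-A/B/C/D) from inter-lysine distances, spacings and lateral
    offsets, measures signed bending and tilting dihedrals across trajectory
    ensembles, profiles interface residues by side-chain mobility and pairwise
    interaction scores, regrafts arbitrary hexamers onto an Arr-A template by
    Kabsch superposition, performs alanine-scan model edits, and reconstructs
    potentials of mean force from umbrella-sampling windows by the weighted
    histogram analysis method (WHAM) with bootstrap errors. A synthetic-data
    module generates C6-symmetric toy hexamers, lattices, bent/tilted
    tri-hexamers, noisy trajectories and biased order-parameter samples with
    machine-readable ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
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
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
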