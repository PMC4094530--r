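Package: shaftshape
Title: Morphometric Mapping of Long-Bone Diaphyses and Genotype-Phenotype
    Congruence Across Ontogeny
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Landmark-free geometric morphometrics of tubular bone shafts
    (morphometric maps of transverse radius of curvature), shape-space and
    ontogenetic trajectory analysis, squared-change parsimony ancestral
    reconstruction, population-genetic distance matrices (Nei standard,
    Cavalli-Sforza-Edwards chord, Hudson Fst, Patterson PC distances),
    Pst/Qst quantitative-genetic differentiation, and stage-wise congruence
    testing of genotypic versus phenotypic distance structure (principal
    coordinates, Procrustes superimposition, Mantel and resampling tests).
    Includes a synthetic-data generator producing diaphysis-like surface
    meshes and drift-model genotypes with known divergence structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    ape,
    vegan,
    jsonlite,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
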