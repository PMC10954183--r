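Package: starchid
Title: Morphometric Species Identification of Starch Grains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying archaeobotanical starch grains to species
    from mixed quantitative and qualitative morphometric measurements.
    Implements compactness, elongation and centricity shape indices with
    categorical binning, ordinal encoding and z-score scaling of a
    15-variable feature matrix, exploratory analyses (principal components,
    a Gini classification tree, stratified train/validation splits,
    confusion matrices), a pooled-covariance linear discriminant classifier
    with Mahalanobis distances and posterior probabilities, and a two-step
    identification pipeline that filters a reference collection to its
    correctly self-classified core before assigning unknown grains to
    species with posterior-probability confidence bins. Includes a
    synthetic-data generator for reference collections and unknowns with
    geometrically consistent size variables and species-specific
    categorical trait frequencies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
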