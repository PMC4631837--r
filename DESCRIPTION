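Package: textureAesthetics
Title: Texture Feature Banks, Laplacian-Score Selection and Hierarchical
    Aesthetic Perception Models for Visual Textures
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes four classical families of low-level texture descriptors
    from raster images (HSV colour statistics, gray-level co-occurrence matrix
    statistics over a distance/orientation grid, Tamura coarseness/contrast/
    directionality, and wavelet sub-band energy signatures), ranks features
    with the unsupervised Laplacian Score on a nearest-neighbour heat-kernel
    graph, and fits a hierarchical three-layer feed-forward model of aesthetic
    texture perception (affective, judgment and emotional layers) by
    cross-validated forward selection over a term library with least-squares
    coefficients. Ships the published reference equations for the eight
    aesthetic antonym pairs, cascade prediction with observed-layer overrides,
    evaluation metrics, and a synthetic-data module that generates parametric
    textures and simulates semantic-differential rating experiments from a
    planted hierarchy, so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    tools,
    stats,
    grDevices,
    utils,
    jsonlite,
    png,
    tiff
Suggests:
    EBImage,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
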