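Package: rgnet
Title: Quantification of Reactive Glial Nets Around Amyloid Plaques
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the stereotyped three-dimensional
    arrangement of microglia and astrocytes around beta-amyloid plaques
    ("reactive glial nets"): radial distance profiling of glial somata
    around plaque centers, the interval-max-GFAP statistic and the derived
    net boundary, intra-net microglia classification, cohort-level
    recruitment correlations, Voronoi tessellation and nearest-neighbor
    analysis of microglial territories in 2D projections, and the supporting
    statistics (Pearson correlation, one-way ANOVA, Tukey-Kramer post hoc,
    Student t tests). Includes a seeded synthetic-data generator emulating
    plaque classes and glial shell geometry with recorded ground truth, a
    voxel-stack renderer, and a segmentation stage (thresholding, 26-connected
    labeling, centroid extraction) so the whole pipeline is testable without
    tissue data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    tiff,
    igraph
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
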