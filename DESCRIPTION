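Package: folliscape
Title: Compartment-Aware Spatial Immunophenotyping for Follicular Lymphoma
    Multiplexed Immunofluorescence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for spatial analysis of multiplexed-immunofluorescence
    tiles of follicular lymphoma biopsies. Provides a synthetic-scene and
    synthetic-cohort generator with programmable spatial coupling and
    survival linkage; a count-regularized convolutional cell detector and a
    small convolutional positive/negative patch classifier; co-expression
    merging of per-marker cell calls into multi-marker phenotypes;
    intra-/inter-follicular compartment geometry with cell densities;
    Voronoi-quadrat Morisita-Horn co-localization and nearest-neighbor
    phenotype profiles; and the association layer (rank-sum tests with
    Benjamini-Hochberg correction, median-split Kaplan-Meier with log-rank,
    Spearman correlation, multivariate Cox regression against FLIPI).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    survival,
    jsonlite,
    yaml,
    tiff,
    withr,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    igraph,
    optparse
Config/testthat/edition: 3
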