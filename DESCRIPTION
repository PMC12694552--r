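Package: grainscan
Title: Micro-CT Grain Structure Phenotyping, QTL Mapping and Candidate Gene Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for three-dimensional phenotyping of cereal grain
    structure from micro-computed-tomography slice stacks. Segments a grain
    into embryo, endosperm, cavity (the air gap between caryopsis and hull)
    and hull by Otsu thresholding, Canny edge detection and deterministic
    region growing; computes fifteen structural traits (tissue volumes,
    surface areas, mean hull thickness and volume ratios) by voxel
    morphometry; summarizes and correlates traits across a recombinant
    inbred line population; maps quantitative trait loci by inclusive
    composite interval mapping with permutation-based thresholds; and
    nominates candidate genes by intersecting QTL support intervals with a
    thresholded differential-expression table. Includes a phantom module
    that generates synthetic CT stacks with ground-truth labels, simulated
    RIL populations with planted QTLs, and simulated DEG tables, so the
    whole pipeline is testable without raw scan or sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    tiff,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    withr,
    jsonlite
Config/testthat/edition: 3
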