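Package: skinmorph
Title: Multiscale Morphometry of Skin Ageing from Microscopy, Profilometry
    and Replica Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Quantitative pipeline linking dermal microstructure to skin
    surface morphology. Computes the Elastin-to-Collagen ratio (R_EC) from
    two-channel (second-harmonic / autofluorescence) microscopy stacks by
    1-D k-means grey-level thresholding, arithmetic surface roughness (Ra)
    from detrended replica height profiles, and skin microrelief
    morphometry (polygon counts, areas, perimeters and the characteristic
    length Lc) by H-minima marker-controlled watershed segmentation.
    Includes cohort statistics (descriptives, Pearson correlation
    matrices, median splits and Mann-Whitney U comparisons) and synthetic
    generators that produce every pipeline input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    EBImage,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
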