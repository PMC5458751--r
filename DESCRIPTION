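Package: chcmorph
Title: Chandelier Cell Axonal Morphometry and Subcellular Synapse Specificity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of chandelier-cell axonal arbors and their
    subcellular innervation of pyramidal-neuron axon initial segments (AIS).
    Provides a synthetic multi-channel confocal stack generator with complete
    ground truth, 3D axon skeletonization with branch-point and length
    morphometry in a soma-anchored region of interest, detection of axonal
    varicosities by size and relative-brightness criteria, AIS segmentation
    with bounding-box filtering and apposition-based varicosity
    classification into AIS and off-target classes, presynaptic-marker
    colocalization calls against a somatic-cytosol background, electron
    microscopy vesicle morphometry (roundness, gold-subtracted density), and
    the accompanying group statistics (Shapiro-Wilk, t tests, one-way ANOVA
    with Bonferroni post hoc, mean +/- SEM reporting).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    tiff,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
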