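Package: EarPheno
Title: Panoramic Image-Based Maize Ear Phenotyping and Quantitative Genetics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested, fully synthetic implementation of a high-throughput
    maize ear phenotyping pipeline based on panoramic surface images. Parametric
    ears (tapered solids of revolution bearing jittered kernel lattices) are
    rendered as rotating frame sequences and ideal panoramas with analytically
    known ground truth for twenty ear and kernel traits. The imaging layer
    performs ear-state detection, color segmentation with morphological cleanup,
    central-strip extraction and cross-correlation stitching; the kernel layer
    segments kernels, builds a Delaunay graph over kernel centroids and counts
    rows and kernels per row by Bellman-Ford shortest paths; the trait layer
    computes lengths, solid-of-revolution surface areas and volumes, a
    non-sphericity shape index, barren-tip measures and color traits. A
    quantitative-genetics layer provides EM-REML variance components and BLUP
    from Henderson's mixed-model equations, broad-sense heritability, per-SNP
    phenotypic variance explained, Spearman correlation with Holm correction,
    subpopulation ANOVA, and SNP minor-allele-frequency/call-rate filtering.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, grDevices, EBImage, png, withr
Suggests: testthat (>= 3.0.0), lme4, jsonlite
Config/testthat/edition: 3
biocViews: ImageAnalysis, Phenotyping, Agriculture, StatisticalMethod
RoxygenNote: 7.3.3
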