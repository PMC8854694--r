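Package: epiquant
Title: Quantitative Analysis of Epiblast Cell Dynamics, Membrane Tension
    FLIM and Intensity Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style toolkit for quantifying epithelial integrity
    in the early post-implantation mouse embryo from live confocal imaging.
    Implements daughter-cell movement classification after apical divisions
    (jitter correction, travel distance and direction angle relative to the
    embryonic-region centre, apical/basal calls, sibling assignment, division
    angle and position), phasor-based fluorescence lifetime imaging analysis
    for the FLIPPER-TR membrane tension probe (pixel binning, background
    thresholding, phasor transform, median filtering, phase lifetime, ROI
    means over a tension-sensitive window), apical F-actin line-profile
    quantification (width-averaged sampling, nuclear normalisation, percent
    rescaling, LOWESS with bootstrap confidence bands), mesoderm migration
    metrics, and the accompanying statistical layer (Fisher's exact test
    with Bonferroni adjustment, one-way and nested ANOVA, Tukey's HSD,
    t-tests, box-plot summaries). A synthetic-data module generates all
    input classes with known ground truth so every stage can be exercised
    and validated without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
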