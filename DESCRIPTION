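Package: flimredox
Title: Simulation and Analysis of NAD(P)H Fluorescence-Lifetime Redox Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying cellular redox state from NAD(P)H
    fluorescence-lifetime imaging (FLIM) of yeast cells. Provides a
    time-correlated single-photon counting (TCSPC) simulator that renders
    fields of yeast cells with known bi-exponential decay parameters,
    Poisson maximum-likelihood fitting of pooled per-cell decay histograms
    with the free-NAD(P)H lifetime fixable at 0.4 ns, automatic cell
    segmentation with pseudocolor lifetime maps, a phasor transform and a
    grid-search oracle for independent verification, group comparison via a
    normality- and variance-driven test-selection tree, and NAD(P)H/NAD(P)+
    ratio arithmetic for chemical redox assays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
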