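Package: ladsim
Title: Individual-Based Simulation of Local Adaptation and Linked Nucleotide Diversity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-time, individual-based Wright-Fisher simulations of
    migration-selection balance on two-patch and linear stepping-stone
    landscapes, with Gaussian stabilizing selection on an additive trait and
    diallelic neutral loci at log-spaced map distances flanking the selected
    loci. Computes within- and between-population nucleotide diversity,
    Weir-Cockerham F_ST and linkage disequilibrium (r^2) from the full
    haplotype state, and implements signature analyses for linked selection:
    diversity-distance regressions, near/far contrasts, background
    calibration, peak detection and width, adaptive-locus differentiation,
    and critical-migration scans. Experiment orchestration over parameter
    grids with deterministic seeding and tidy TSV outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vcfR,
    withr
Config/testthat/edition: 3
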