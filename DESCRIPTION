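Package: phylosucc
Title: Phylogenetic Turnover of Woody Plant Communities Across Successional
    Stages and Phylogenetic Depths
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes phylogenetic turnover of communities sampled along a
    successional chronosequence into spatial (within-stage) and temporal
    (between-stage) components using the Hardy-Senterre statistics PIst
    (presence/absence) and Bst (abundance), tests them against tip-shuffling
    and clade-restricted null models, profiles turnover across phylogenetic
    depths (divergence-time thresholds), identifies clades over-represented in
    individual plots, relates turnover to environmental distances by
    permutation regression with spatial-distance partialling, and estimates
    phylogenetic signal in species traits (Blomberg's K, Pagel's lambda,
    Abouheif/Moran's I). Includes a synthetic-data generator emulating a
    staged chronosequence with environmental filtering scenarios, used as the
    test harness for every analysis step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    phytools,
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
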