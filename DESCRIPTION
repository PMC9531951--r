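Package: smfsid
Title: Classification and Bayesian Identification of Membrane Proteins from
    Single-Molecule Force Spectroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for atomic force microscopy (AFM)
    single-molecule force spectroscopy (SMFS) force-distance curves harvested
    from native membranes: preprocessing and spurious-trace filtering,
    worm-like-chain (WLC) contour-length transformation and quality scoring,
    alignment-based pairwise trace distances, density-peak clustering with
    area-of-similarity refinement and merging, and Bayesian molecular
    identification of each unfolding cluster against a proteome table built
    from mass-spectrometry abundances and membrane topology. Includes a
    synthetic WLC sawtooth curve simulator so the whole pipeline can be
    exercised without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
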