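Package: fodm
Title: Fuzzy Oil Drop Analysis of Hydrophobicity Distributions in Protein Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encapsulates a protein structural unit (complex, chain, domain or
    beta-sheet) in a fitted 3D Gaussian envelope and compares the theoretical
    (T), observed (O), uniform (R) and environment-modified (M) per-residue
    hydrophobicity distributions via Kullback-Leibler divergence. Reports the
    relative-distance statistic RD and the environmental modification
    magnitude K in unit mode (own envelope) and fragment mode (renormalized
    sub-profiles), correlates profiles with crystallographic B-factors with a
    stepwise outlier-elimination procedure, generates synthetic micelle-like,
    inverted and uniform test structures, and ships a declarative study
    configuration for the serpin conformational forms.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
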