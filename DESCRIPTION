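Package: mytikit
Title: Mining and Characterization of Mytilin-Like Antimicrobial Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering and characterizing mytilin-like CS-alpha-beta
    antimicrobial peptide precursors in mussel transcript sets. Implements an
    iterative translated homology screen over six-frame ORFs, tripartite
    precursor segmentation (signal peptide / mature peptide / anionic
    C-terminal extension), cysteine-array classification and disulfide
    topology assignment, net-charge and sliding-window isoelectric-point
    profiling, Hobohm algorithm-2 redundancy reduction over BLOSUM62
    distances, profile hidden Markov model construction with Gumbel E-value
    calibration, and neighbor-joining phylogenies. Ships the mature peptide
    set of thirty mussel mytilins as a packaged fixture and a synthetic-data
    generator that emulates mytilin precursor statistics for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
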