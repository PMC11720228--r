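Package: ringkit
Title: RING E3 Ligase Domain Grammar Scanning, Duplication and Salt-Stress Expression Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide characterization of RING-type E3 ubiquitin
    ligase gene families, built around a bounded-gap metal-ligand grammar for
    detecting and classifying zinc-finger RING domains (RING-H2, RING-HCa/b,
    RING-v, RING-C2, RING-S/T, RING-D, RING-G) in protein sequences.
    Includes spacing-pattern profiling between metal-ligand residues,
    molecular weight and theoretical isoelectric point computation
    (Bjellqvist-style pK set), Nei-Gojobori (1986) Ka/Ks estimation with
    Jukes-Cantor correction and selection-class calling for duplicate gene
    pairs, tandem-duplicate classification from gene order, salt-stress
    differential-expression set logic across time points with duplicate-pair
    concordance, Livak 2^-ddCt relative expression, and fully seeded
    synthetic-data generators with ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    jsonlite,
    generics,
    stats,
    tools,
    utils,
    Biostrings,
    rtracklayer,
    optparse
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    withr
Config/testthat/edition: 3
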