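Package: rotamerph
Title: Histidine Rotamer Surveys, pH Association and Phospho-Decay Kinetics
    for HisKA Histidine Kinases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to test whether crystallization pH gates the side-chain
    conformation of the phosphorylatable histidine in HisKA-family sensor
    histidine kinases. Reads PDB/mmCIF coordinate files, measures chi-1
    side-chain dihedrals and classifies gauche-/gauche+/trans rotamers per
    subunit and alternate conformer, joins calls to crystallization-pH
    metadata, tests pH-rotamer association with an exact 2x2 test
    implemented from log-factorials, detects His-anion (sulfate)
    coordination, superposes complexes by the Kabsch algorithm, and fits
    first-order phospho-histidine decay to estimate half-lives. Ships a
    curated survey manifest of deposited HisKA structures and a
    synthetic-structure and decay-curve generator so the whole pipeline is
    testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
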