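Package: radt
Title: Residue-Level Protein-Protein Interface Prediction with
    Alternating Decision Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for machine-learning prediction of
    transient protein-protein interface residues from crystal structures.
    Parses PDB files (including COMPND, REMARK 2, SSBOND, CONECT and BIOMT
    records), applies monomer quality filters and sequence-identity
    deduplication, maps monomers to complexes and labels interface residues
    by a 4.5 Angstrom atom-pair contact rule, computes per-residue surface
    and physicochemical features, rebalances classes by random
    under-sampling, trains boosted Alternating Decision Trees evaluated by
    leave-one-protein-out cross-validation, and searches feature subsets
    with a genetic algorithm accelerated by Hoeffding racing against an
    elite. Includes deterministic synthetic structure and planted-signal
    generators so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
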