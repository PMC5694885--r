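Package: phagehead
Title: Prohead Protease Cleavage-Site Inference and Spectral-Count
    Abundance for Phage Virion Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers prohead-protease maturation cleavage sites in phage
    virion proteins from bottom-up (GeLC-MS/MS) peptide evidence and
    estimates virion-protein stoichiometry by mass-normalized spectral
    counting (SC/M). Classifies identified peptides against an in-silico
    tryptic digest to find semi-tryptic termini, aggregates them into
    candidate cleavage sites, matches sites against protease cleavage-motif
    models (A-X-E and relatives), infers maturation boundaries from
    coverage and gel migration, computes mature-form masses, reassigns
    translational start sites from upstream-mapping peptides, calibrates
    copy-number estimates against reference stoichiometry, and compares
    wild-type and mutant virion proteomes. A seeded synthetic-data
    generator emulates a virion proteome with planted cleavage sites and
    gel-slice spectral counts so that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
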