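Package: tsafinder
Title: Proteogenomic Discovery of Tumor-Specific Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds personalized tumor protein search databases from somatic
    variants, unannotated splice junctions, and gene fusion breakpoints;
    filters mass-spectrometry peptide-spectrum matches through a multi-stage
    tumor-specificity cascade with normal-tissue subtraction and a
    conservation-checked filter ledger; and validates surviving peptides by
    regressing observed retention times on a sequence-derived hydrophobicity
    index. Includes a seeded synthetic-fixture generator (toy genome,
    annotation, events, normal catalogs, and simulated PSM tables) so every
    pipeline stage is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    vcfR,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    rlang,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
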