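Package: repairsieve
Title: Rare Germline Variant Prioritization in DNA Repair Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for prioritizing rare germline variants in DNA
    repair genes from annotated cohort call sets. Reads VCF files carrying
    VEP-style CSQ annotations, intersects dual-caller call sets, restricts to a
    DNA-repair gene panel, and applies a two-round filtering cascade over CADD
    deleteriousness scores, gnomAD allele frequencies, consequence classes and
    REVEL missense pathogenicity scores, with explicit missing-value retention
    semantics. Includes per-patient carrier aggregation, novelty detection and
    cohort summary statistics, a planted-truth synthetic cohort generator, and
    bundled fixtures transcribing a published early-onset breast cancer screen.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    tools,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
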