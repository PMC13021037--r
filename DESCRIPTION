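Package: raretriage
Title: Panel-Restricted Rare-Variant Triage and Clinical Classification for
    Annotated Exomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Triage of VEP-annotated whole-exome variants against curated
    disease-gene panels: canonical-transcript consequence selection,
    a multi-stage rarity filter with a PopMax allele-frequency threshold
    across gnomAD subpopulations, an in-silico deleteriousness consensus
    over standalone prediction tools and CADD, and a clinical-precedence
    classifier that resolves ClinVar and UniProt assertions into a
    five-tier interpretation plus a predicted-deleterious tier. Includes
    cohort summarisation and export, generic hypergeometric
    over-representation analysis over GMT term-gene maps, and a seeded
    synthetic annotated-cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
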