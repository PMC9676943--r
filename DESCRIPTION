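Package: mitofam
Title: Family-Based Mitochondrial Genome Heteroplasmy and Haplogroup Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for family-based analysis of the mitochondrial genome from
    deep-sequencing variant tables: multi-caller consensus calling of low-level
    heteroplasmic variants with base/mapping-quality, mono-allelicity and
    strand-odds-ratio (SOR) filters; mtDNA haplogroup classification from a
    diagnostic marker panel with U5a/U5b refinement; triage of private variants
    by pathogenicity thresholds (MITOMAP status, CADD, MToolBox, MitoTip) and
    OXPHOS-complex burden tables; mother-offspring de novo heteroplasmy
    detection with mutational-rate estimation and a trio nuclear de novo
    genotype filter; and family-matched cohort statistics (Benjamini-Hochberg
    FDR on frequency tables, rank tests, stratum-conditional logistic
    regression and family-clustered mixed logistic models with stepwise
    selection). A seeded synthetic family-cohort generator emulates every
    required input so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    survival,
    lme4,
    nortest,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
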