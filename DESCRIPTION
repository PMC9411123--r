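Package: splicedx
Title: Paired DNA-RNA Splicing Analysis for Hereditary Cancer Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and classifies aberrant splicing events from splice-junction
    count tables, quantifies them as percent-spliced-index (PSI) values against a
    pool of healthy-donor controls, annotates DNA variants in HGVS-style cDNA
    coordinates with position bins and splice-site strength scores, infers the
    splicing mechanism behind a variant, applies clinical reporting-range masking
    and quality filters, integrates RNA evidence into variant reclassification,
    and summarises cohorts. Includes a synthetic-data generator emulating the
    statistical structure of a paired DNA-RNA diagnostic cohort so that every
    stage is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    withr,
    stats,
    utils,
    Biostrings,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
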