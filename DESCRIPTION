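Package: varcohort
Title: Comparison of Whole-Genome Variant Cohorts Across Resequenced Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for comparing short-variant call sets (SNPs and short
    insertions/deletions) across several resequenced lines of the same
    cultivar or strain. Implements quality/coverage/type-consistency
    filtration of a multi-line variant table, classification of variants by
    line-sharing pattern, per-line mutation-rate and substitution-spectrum
    (transition/transversion) summaries, windowed variant-density profiles
    with group contrasts, a single-effect coding-consequence classifier with
    SNPEff-style impact categories, and a seeded synthetic cohort generator
    with a known truth table so every pipeline stage can be exercised without
    raw sequencing data.
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
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    vcfR,
    rtracklayer,
    Biostrings,
    stats
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
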