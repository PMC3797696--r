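Package: chromscan
Title: Chromosome-Centered Analysis of Somatic Copy-Number and Uniparental Disomy Lesions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for chromosome-centered analysis of somatic lesions in
    cancer cohorts genotyped by SNP microarrays and exome sequencing.
    Summarises deletion, gain and uniparental-disomy (UPD) segments across a
    cohort, tests lesion-phenotype associations with an exact Fisher test
    built from hypergeometric point probabilities, detects common deleted
    regions (CDRs) by sweep-line support profiling, calls focal copy-number
    events from per-base exome depth via chromosome-normalised log2 ratios
    against a control-pool median reference, annotates coding-sequence tandem
    duplications and single-nucleotide variants at residue level, and
    classifies the genetic mechanism acting on a mutant allele (heterozygous,
    UPD-homozygous, gain-amplified, hemizygous, compound-heterozygous) from
    variant allele fractions and subclone colony genotyping. Seeded synthetic
    generators emulate every input so the whole pipeline is testable without
    external data.
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
    GenomicRanges,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
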