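Package: gtseqr
Title: SNP Panel Development, Amplicon Genotyping and Validation for
    GT-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for building and validating Genotyping-in-Thousands by
    sequencing (GT-seq) SNP panels: candidate SNP selection from genotype
    matrices, thermodynamic screening of multiplex primer pools, allele-ratio
    genotype calling from amplicon FASTQ reads, cross-method genotype
    concordance reports, and population-genetic validation statistics
    (observed/expected heterozygosity, Fis, pairwise Weir-Cockerham Fst with
    bootstrap confidence intervals).  A synthetic-data generator simulates
    structured diploid populations under the Balding-Nichols model and emits
    amplicon reads with sequencing error and allelic dropout, so the whole
    pipeline can be exercised end to end without real samples.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    knitr,
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    yaml
Config/testthat/edition: 3
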