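Package: wssgwas
Title: Weighted Single-Step GWAS for Repeated-Record Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-step genomic BLUP (ssGBLUP) and weighted single-step
    genome-wide association analysis (WssGWAS) for quantitative traits with
    repeated records, as used in pig and other livestock breeding. Builds
    pedigree numerator relationship matrices and their inverses, VanRaden
    genomic relationship matrices with SNP-specific weights, and the combined
    H-inverse; estimates variance components of the repeatability animal model
    by EM/AI-REML; iterates the SNP-weighting loop that converts genomic
    breeding values into SNP effects; summarises genetic variance by 0.4 Mb
    SNP windows; and selects, merges and annotates candidate QTL regions.
    Includes a synthetic-data generator (pedigree, LD-structured genotypes,
    QTL architectures, repeated-record phenotypes) so the whole pipeline is
    testable without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
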