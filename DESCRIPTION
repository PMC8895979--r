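Package: dormgwas
Title: Pool-GWAS of Reproductive Dormancy from Extreme-Phenotype Pools
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for a pooled-sequencing genome-wide association
    study of reproductive dormancy in isofemale Drosophila strains. Covers
    strain-level dormancy phenotyping at two temperature regimes, selection of
    extreme dormant/non-dormant strain pools, synchronized-pileup (sync) allele
    count processing (masking, down-sampling, replicate merging, biallelic
    extraction), chi-squared allele-frequency association with Haldane-Anscombe
    log odds ratios, exhaustive label-permutation null distributions with
    empirical false discovery rates, candidate SNP and gene calling, and a
    coverage-window screen for structural polymorphisms. A synthetic-data
    generator emulates the isofemale-strain study design so every stage is
    testable without the original sequencing reads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    ggplot2,
    rlang,
    S4Vectors,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
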