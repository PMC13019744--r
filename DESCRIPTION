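Package: rohscan
Title: Runs of Homozygosity, Genomic Inbreeding and ROH Islands from
    SNP-Array Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects runs of homozygosity (ROH) in diploid SNP-array
    genotype panels with a sliding-window scan and a
    false-positive-controlled minimum-SNP threshold, applies standard
    array quality control (call rate, minor allele frequency,
    Hardy-Weinberg exact test, individual missingness), summarises ROH by
    length class and chromosome, estimates genomic inbreeding
    coefficients (F_ROH overall and per length class; excess-homozygosity
    F_HOM) with their Pearson correlations, identifies ROH islands as
    runs of top-percentile SNPs and annotates them with overlapping
    genes. Includes a synthetic-panel generator that plants
    identical-by-descent homozygous tracts of known length so every
    pipeline stage can be validated against ground truth. Reads and
    writes PLINK PED/MAP and binary BED/BIM/FAM formats, and reads VCF,
    GFF3 and BED gene models.
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
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
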