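Package: rohscape
Title: Runs of Homozygosity, Genomic Inbreeding and Selection-Signature
    Scans for Multi-Sample Genotype Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects runs of homozygosity (ROH) in multi-sample diploid
    genotype panels with a PLINK-style sliding-window scanner at
    configurable window scales, computes the genomic inbreeding
    coefficient F_ROH, derives private, group-shared and consensus ROH
    regions by position-set algebra on homozygous variants, estimates
    sequencing genotype error rates against SNP-array calls (including a
    robust false-positive rate inside long array ROH), computes windowed
    site-frequency-spectrum neutrality statistics (Tajima's D, Fu & Li's
    D and F, Fay & Wu's H, Zeng's E), and intersects ROH regions with
    gene annotations.  Ships a synthetic-panel generator with planted
    autozygous tracts so the whole pipeline is testable against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    methods,
    purrr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
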