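Package: stochmeth
Title: Stochastic Cytosine-Methylation Change Analysis for MeDIP-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Bin-level analysis of cytosine-methylation change between two
    MeDIP-seq conditions (control versus knockdown). Computes normalized
    Diff/Sum change statistics per 0.2 kb genomic bin, quantifies the
    stochasticity of gain versus loss of methylation by binary Shannon
    entropy, scans sequences with position weight matrices using exact
    dynamic-programming p-values and tests transcription-factor binding-site
    enrichment in differentially methylated bins, classifies binding-site
    peaks into repeat-free-motif and motif-free-repeat classes with 10 kb
    flank-asymmetry analysis, and classifies allelic imbalance in
    methylation at heterozygous SNPs into parent-of-origin categories.
    A synthetic diploid MeDIP read generator with full ground truth drives
    every stage so the pipeline is testable without sequencing data.
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
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
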