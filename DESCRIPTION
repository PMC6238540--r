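Package: asdecay
Title: Allele-Specific mRNA Decay Analysis for F1-Hybrid Time-Course RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates allele-specific differences in mRNA decay rate (ASD)
    from SNP-level allelic read counts collected over a transcription-arrest
    time course in F1 hybrids. Fits a binomial logit-linear model of the
    allelic read fraction against time, assesses per-gene significance by
    bootstrap resampling of SNP loci, and estimates the false discovery rate
    by gene-label permutation. Also calls allele-specific steady-state
    abundance (ASA) from 0 h counts, classifies genes jointly by ASD/ASA,
    filters SNP loci with allelic mapping or assignment bias via Fisher's
    exact test, computes allele-level sequence features (SNP density, miRNA
    seed sites, windowed secondary-structure differences, codon adaptation
    index), and ships a synthetic-data generator with full ground truth for
    power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    Biostrings,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
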