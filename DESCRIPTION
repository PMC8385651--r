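Package: sdrase
Title: Sex-Associated Allele-Specific Expression Analysis for a Plant Sex-Determining Region
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect sex-associated allele-specific expression (ASE) in
    a dioecious plant's sex-determining region (SDR) from paired genomic and
    transcriptomic allele depths. The package calls heterozygous sites from DNA
    allele depths, classifies per-gene allelic expression from cDNA allele
    depths across tissues, tests sex association of monoallelic expression with
    an exact test across a cohort, scans binned whole-genome coverage for
    male-hemizygous (Y-specific) intervals, and provides bulk-expression
    utilities (counts-per-million, TMM normalization, a fold-change screen, and
    Spearman-correlation distance matrices). A synthetic-cohort generator with
    full ground truth emulates the study design (one male and one female with
    whole-genome and three-tissue RNA-seq, plus a deep targeted-amplicon panel
    of ten males and ten females), so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    jsonlite,
    yaml,
    vcfR,
    edgeR,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
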