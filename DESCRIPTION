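Package: bivalseq
Title: Sequential ChIP-Seq Analysis of Bivalent Mononucleosomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide analysis of bivalent chromatin from
    sequential (re-)ChIP-seq of mononucleosomes: SICER-style island calling
    tuned for narrow (H3K4me3) and broad (H3K27me3) histone marks,
    promoter classification into bivalent / mark-exclusive classes,
    input-normalized TSS and enhancer coverage profiles, and CpG-density,
    expression and DNA-methylation stratifications. Includes a synthetic-data
    generator that simulates a cell population with zonal mark domains,
    a controllable fraction of truly bivalent TSS-proximal nucleosomes,
    primary-IP flow-through, and a nucleosome-depleted region, so that
    every stage of the pipeline can be verified against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
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
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
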