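Package: ervpop
Title: Discovery, Genotyping, and Evolutionary Dating of Endogenous
    Retrovirus Insertions
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Population-scale analysis of a recently active endogenous
    retrovirus (ERV) lineage from short-read sequencing data. Detects
    non-reference ERV insertions from anchored read pairs with greedy
    overlap-layout-consensus junction assembly and target-site-duplication
    resolution, detects unfixed reference insertions from insert-size
    deviation, reconstructs insertion and pre-insertion alleles and computes
    mapping-quality-based genotype likelihoods across diploid cohorts, dates
    proviruses by 5'-3' LTR divergence under a neutral molecular clock (and
    identical-LTR haplotype clusters by concatenated length), tests for
    depletion of insertions near gene models by permutation, and annotates
    proviral consensus sequences for shared defects and Nei-Gojobori dN/dS.
    A seedable synthetic-data module generates references, insertion truth
    sets, diploid cohorts, and paired-end reads so the whole pipeline is
    testable at desk scale.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors,
    stats,
    utils,
    withr
Suggests:
    VariantAnnotation,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
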