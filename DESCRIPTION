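Package: sigstrata
Title: Mutational-Signature-Based Tumor Stratification from Multi-Caller
    Somatic Variant Calls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds transcription-strand-aware single-base-substitution
    mutation catalogs (96/288/384 channels) from per-caller somatic variant
    calls, screens out samples with rare mutation spectra, extracts de novo
    mutational signatures by replicated Kullback-Leibler nonnegative matrix
    factorization with stability-based selection of the number of
    signatures, clusters samples on relative signature exposures with a
    cross-caller stability consensus, attributes reference signatures by
    nonnegative least squares with bootstrap confidence intervals and
    zero-in-CI pruning to limit over-attribution, dissects APOBEC
    mutagenesis into APOBEC3A-like (YTCA) and APOBEC3B-like (RTCA)
    tetranucleotide contexts, and ships a synthetic-cohort simulator with a
    ground-truth ledger and a mutation-burden-dependent over-attribution
    benchmark.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    cluster,
    stats,
    utils,
    jsonlite,
    vcfR,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics,
    rtracklayer
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
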