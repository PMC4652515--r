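Package: kmerphylo
Title: Reference-Free Tumor Cell Phylogenetics from k-mer Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers distance-based phylogenies of single tumor cells from raw
    short-read sequencing data without aligning to a reference genome. Per-cell
    k-mer spectra are counted from FASTQ, corrected for amplification and
    sequencing noise (sparse-occurrence and present-in-all-samples filters,
    duplicate-cell detection), normalized by total sum scaling, and reduced by
    interquartile-range filtering and Wilcoxon rank-sum differential-abundance
    selection with Bonferroni correction. Euclidean and Bray-Curtis
    dissimilarities feed neighbor-joining trees with feature-bootstrap
    majority-rule consensus, a permutation-tested within/between class
    separation statistic, and a cross-validated classification harness. A
    clone-structured read simulator with copy-number profiles, whole-genome
    amplification unevenness, and per-base error makes the pipeline testable
    end to end on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    Biostrings,
    ape,
    vegan,
    e1071,
    rpart,
    tibble,
    dplyr,
    generics,
    rlang,
    stringi,
    ggplot2,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
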