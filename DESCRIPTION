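Package: somaTE
Title: Somatic Transposable-Element Insertion and Expression Analysis for
    Matched Tumor-Normal Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing somatic transposable-element (TE) activity in
    matched normal/tumor sample pairs. Implements two-caller consensus merging
    of TE insertion calls with read-support filtering, partitioning of each
    patient's insertions into shared (germline-like) versus tissue-specific
    sets, identification of cohort-private insertions, population allele
    frequency annotation against a reference panel with private/low/high
    binning, observed-versus-expected L1 enrichment statistics (Fisher exact
    and Kolmogorov-Smirnov tests), genome-feature driver screening against
    gene models, enhancers and tumor-suppressor lists, and TE expression
    comparison with an expectation-maximization assignment of multi-mapped
    reads. A fully parameterised synthetic cohort generator provides truth
    sets, emulated caller outputs, reference panels, genome features and
    expression tables so that every stage of the pipeline can be validated
    end to end without access to restricted sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
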