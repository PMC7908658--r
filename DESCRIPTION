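Package: trftargets
Title: Prediction of mRNA Targets of tRNA-Derived Fragments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts messenger RNA targets of tRNA-derived fragments (tRFs)
    from Argonaute chimeric reads. Decomposes CLASH/CLEAR-CLIP chimeric reads
    into a catalog tRF and a 3'-UTR target fragment, scans 3'-UTRs for
    perfect seed matches (tRF positions 2-7), computes sequence-context,
    transcript, tRF and duplex-thermodynamics features for every site, and
    trains a support vector machine site classifier with genetic-algorithm
    feature selection under fivefold cross-validation. Site probabilities
    are combined per transcript by a noisy-OR rule. Two independent
    predictors are included: a binomial overrepresentation test against an
    order-1 Markov background with Benjamini-Hochberg adjustment, and a
    conservation-score classifier consuming a per-base score track. A
    synthetic-data generator with known ground truth makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    e1071,
    pROC,
    rtracklayer,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
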