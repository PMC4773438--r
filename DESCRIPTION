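Package: ampliclone
Title: Indel Quantification, Lineage Tracking and Rearrangement Detection
    for Multiplexed CRISPR Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of deep paired-end amplicon sequencing from multiplexed
    CRISPR/Cas9 editing experiments in tumours. Provides a long-deletion-aware
    semi-global affine-gap aligner so that single deletions of several hundred
    base pairs are represented as one event rather than fragmented alignments;
    left-normalized indel calling with mutant-read-frequency (MRF)
    quantification and read-support filtering; ploidy-constrained assignment
    of allele frequencies to integer chromosome copies; zygosity
    classification (complete versus partial gene inactivation); clonal
    lineage tracking of metastases via CRISPR indel signatures; off-target
    screening; enumeration and detection of CRISPR-induced deletion and
    translocation junctions with breakpoint-at-cut-site verification; a
    Surveyor gel-band estimator; and a synthetic cohort generator with full
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
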