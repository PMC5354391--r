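Package: lockscape
Title: Differential Analysis of Broad H3K9me2 Chromatin Domains
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Genome-wide analysis of large organized chromatin K9 (LOCK)
    domains of H3K9me2 from scored enriched-domain calls: multi-resolution
    window binning with alignability-deadzone masking and mean
    normalization, genome-wide Pearson correlation and complete-linkage
    clustering of samples, classification of conserved-high / variable /
    conserved-low (Red/Yellow/Green) zones across a sample panel,
    differential-LOCK (dLOCK) calling between sample categories by pairwise
    Sum-Log-Ratio scoring with empirical quantile thresholds, feature
    fold-enrichment and gene-set summaries, and a synthetic-data generator
    with planted ground truth for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    S4Vectors,
    ape,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
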