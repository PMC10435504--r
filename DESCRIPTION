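Package: spaceclone
Title: Spatial Subclonal Architecture of Multiple Myeloma from Paired-Site
    Bulk and Single-Cell Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies spatial tumor heterogeneity between paired bone
    marrow sites (random iliac-crest aspirate versus focal lesion) in
    multiple myeloma. Estimates per-variant cancer clonal fractions from
    bulk whole-genome allele counts via mutation copy number and
    maximum-likelihood multiplicity, classifies paired-site SNVs and copy
    number aberrations into shared, unshared and enriched categories,
    detects CNA-defined subclones in single-cell RNA and ATAC matrices
    supervised by bulk copy-number segments, computes single-cell peak
    co-accessibility against a shuffled-permutation background, applies
    T-cell-receptor clonotype expansion rules, and compares paired-site
    microenvironment composition with exact signed-rank tests. Ships a
    synthetic paired-site cohort generator with known ground truth so the
    whole pipeline is testable without controlled-access patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Matrix,
    jsonlite,
    cluster,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
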