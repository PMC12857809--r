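Package: epimm
Title: Quantifying Immune-Epithelial Crosstalk in Spatial and Single-Cell Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistics and simulation tools for immune-epithelial crosstalk in
    chronically inflamed nasal tissue. Implements the geometric interaction odds
    ratio (OR*) on pruned Delaunay proximity graphs with a permutation null,
    ligand-receptor weighted co-expression interaction scores, gene-signature
    scoring (binned-control module scores and single-sample rank-enrichment),
    threshold-based Wilcoxon marker tests, cross-region Spearman correlation,
    and the basal transition continuum (differential-gene PCA with a loess
    spline coordinate and external-profile projection), together with seeded
    generators of spatial point patterns, coupled region expression, and
    count cohorts with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deldir,
    jsonlite,
    Matrix,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
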