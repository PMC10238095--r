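Package: cccrc
Title: Tumor-Microenvironment Subtyping of Colorectal Cancer from Signature Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-sample gene-set enrichment scoring (GSVA and ssGSEA) of
    tumor-microenvironment signature panels, consensus k-medoids subtype
    discovery with CDF/delta-area model selection, nearest-shrunken-centroid
    subtype classification with cross-validated threshold selection,
    one-vs-rest and pairwise differential analysis across expression,
    methylation and protein layers, detection of monotone cross-subtype
    evolution patterns and the derived evolution score, a nearest-template
    pre-clinical classifier with a cancer-cell-intrinsic gene filter, and
    whole-slide patch-composition quantification. Seeded synthetic-cohort
    generators with planted ground truth support end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    matrixStats,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
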