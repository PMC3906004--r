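Package: bbmomics
Title: Integrated Copy-Number, Expression and Methylation Analysis of
    Breast-Cancer Brain Metastases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of an integrated multi-omics workflow
    for breast-cancer brain metastasis cohorts: circular-binary-style copy-number
    segmentation with permutation split testing, ADM-2-style per-sample
    aberration calling, GISTIC-style G-score recurrence with permutation FDR,
    tri-group differential expression against dual non-neoplastic references,
    nearest-centroid intrinsic subtyping, Mann-Whitney differential methylation
    with delta-beta effect gating, a CpG-island hypomethylator signature,
    per-sample multi-layer congruency integration nominating candidate tumor
    suppressors and oncogenes, ROC biomarker comparison, and delta-delta-Ct
    quantification. A matched synthetic cohort generator with planted, recorded
    ground truth makes every stage testable without array downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    Rcpp,
    S4Vectors,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
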