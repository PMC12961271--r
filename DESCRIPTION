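Package: tagine
Title: Taxonomy-Aware Feature Engineering for Microbiome Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements TAGINE, a fast taxonomy-aware feature engineering
    algorithm for binary classification of microbiome samples. Starting from
    coarse taxonomic clades, the algorithm iteratively splits a clade into its
    child clades only when an AIC comparison of two logistic regressions shows
    that the split improves label prediction, and prunes children whose
    coefficients are not significant. The result is a compact, non-nested,
    multi-level clade feature set together with the pruned taxonomic tree it
    derives from. Includes compositional preprocessing (rare-feature
    filtering, relative-abundance normalization, half-minimum pseudocounts), a
    lineage-structured synthetic data generator with planted class signal, and
    a benchmarking harness with repeated stratified splits, random-forest
    AUC-ROC, Nadeau-Bengio corrected paired t-tests and Benjamini-Hochberg
    FDR control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    ranger,
    stats,
    utils,
    withr
Suggests:
    biomformat,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
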