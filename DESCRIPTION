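Package: subtypeAWA
Title: Comprehensive Evaluation of Multi-Omics Cancer Subtyping Methods
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A benchmarking harness for multi-omics clustering algorithms
    used in cancer molecular subtyping. Computes internal cluster validity
    indices (silhouette, Calinski-Harabasz, Dunn) and clinical relevance
    metrics (k-sample log-rank test, enriched clinical parameter counts),
    harmonizes raw metric values across methods onto a common 0-10 score
    scale, and aggregates them into the accuracy-weighted average (AWA)
    index with configurable internal/clinical weights. Includes the
    per-omics preprocessing rules common in TCGA-style studies
    (copy-number deduplication, methylation beta filtering, log transform,
    MAD and variance feature filtering, missingness filtering, imputation,
    standardization) and a synthetic multi-omics generator with known
    subtype structure, subtype-dependent survival and controllable
    clinical-covariate enrichment, so every evaluation stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests:
    cluster,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
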