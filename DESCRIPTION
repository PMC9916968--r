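Package: taavet
Title: Systematic Vetting and Prioritization of Tumor-Associated Antigens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the systematic selection of tumor-associated antigens
    (TAAs) as targets for T cell-based immunotherapy of epithelial ovarian
    cancer. Implements a three-step expression-based candidate cascade
    (neoantigen exclusion, healthy-tissue TPM tiering, tumor-cohort FPKM
    gating) with auditable per-stage reports, a weighted multi-criterion
    scoring rubric with 10-point normalization and competition ranking,
    immunohistochemistry Q-Score quantification of tissue-microarray
    staining, a clinical association toolkit (Fisher's exact test, Pearson's
    chi-squared test, Spearman correlation, Kaplan-Meier estimation,
    two-group log-rank test), molecular-subtype differential expression via
    Kruskal-Wallis and Dunn-Bonferroni post-hoc tests, and synthetic-data
    generators with planted ground truth so every stage is testable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
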