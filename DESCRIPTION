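Package: csfsig
Title: Multi-Cohort CSF Proteome Biomarker Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable implementation of a multi-cohort cerebrospinal
    fluid (CSF) proteome biomarker-discovery workflow for Alzheimer's disease
    (AD): quality control and coefficient-of-variation reporting for replicate
    plate designs, biochemical AD classification rules (t-tau/amyloid cutoffs
    and the Hulstaert index), per-cohort differential abundance with a SAM
    statistic and permutation-based false discovery rates, cross-cohort
    directional-consistency signatures, protein-covariate correlation and
    covariate-adjusted regression with IQR-scaled estimators, rank-based 1D
    annotation enrichment, cross-study overlap statistics, and decision-tree
    feature selection with k-fold boosted-tree ensemble evaluation. Ships a
    synthetic multi-cohort data generator with ground truth so every stage is
    testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
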