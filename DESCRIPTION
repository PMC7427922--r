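Package: hfpefmap
Title: Phenomapping of Subclinical Diastolic Dysfunction Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end phenomapping pipeline for cohorts of patients with
    subclinical diastolic dysfunction followed for progression to heart
    failure with preserved ejection fraction (HFpEF). Provides mixed-type
    cohort encoding (one-hot), iterative singular-value-decomposition
    imputation of missing clinical data, agglomerative hierarchical
    clustering on squared Euclidean distances with outcome-homogeneity and
    purity based selection of the cluster count, per-cluster comparative
    statistics (chi-square, one-way ANOVA, Newman-Keuls and Duncan multiple
    comparisons), logistic risk modelling with prevalence cutoffs and
    alternating two-fold cross-validation, and Kaplan-Meier disease
    trajectory summaries. Includes a synthetic-cohort generator emulating
    the scale and structure of a phenomapped diastolic-dysfunction cohort
    so the full pipeline is testable without patient-level data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
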