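Package: cmtf
Title: Sparse Coupled Matrix-Tensor Factorization for Longitudinal
    Clinical Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multi-block latent factor analysis for cohorts observed as a
    longitudinal biomarker tensor (subjects x variables x visits) coupled to
    baseline-clinical and SNP-genotype matrices through a shared subject
    mode.  Implements masked CP/PARAFAC alternating least squares, sparse
    coupled matrix-tensor factorization with L1 soft-thresholding on the
    variable modes, permutation-based pattern-to-pattern association tests,
    and split-half component stability analysis, together with a synthetic
    cohort generator with known ground-truth factors and deterministic
    derivation of standard clinical codings (insulin-dose-adjusted HbA1c,
    partial remission, diabetic ketoacidosis grades, HLA-DQB1 risk groups,
    autoantibody positivity, additive genotype coding).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
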