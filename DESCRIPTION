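Package: slassosum
Title: Smoothed Lassosum Polygenic Risk Scores and Integrated Risk Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits polygenic risk scores and integrated risk models by
    minimizing a smoothed version of the Lassosum objective function.
    The non-differentiable L1 penalty is replaced by its Nesterov
    smoothing with the entropy prox-function, which yields a strictly
    convex objective with a closed-form gradient that can be minimized
    by quasi-Newton methods, together with an a-priori bound on the
    deviation from the unsmoothed objective. Supports both
    summary-statistics input (GWAS effect sizes plus an external
    linkage-disequilibrium reference panel) and individual-level
    genotype data, covariate residualization for integrated risk
    models, PLINK bed/bim/fam and dosage-matrix readers, evaluation
    metrics (mean absolute residual, AUC, correlation), and a
    synthetic-cohort simulator with block-autoregressive linkage
    disequilibrium for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
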