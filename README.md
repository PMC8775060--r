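# slassosum

Polygenic risk scores (PRS) and integrated risk models (IRM) fitted by
minimizing a **smoothed Lassosum objective**.

## What problem this solves, and for whom

A PRS predicts disease risk from a weighted sum of allele dosages; an IRM
adds epidemiological covariates such as age and sex. The Lassosum
formulation of the penalized fit,

```
L(β) = yᵀy + (1−s) βᵀ XᵣᵀXᵣ β − 2 βᵀr + s βᵀβ + 2λ ‖β‖₁ ,
```

depends on the data only through the SNP-wise correlations `r = Xᵀy` and an
LD (linkage-disequilibrium) matrix `XᵣᵀXᵣ`, so it can be fit either from
**GWAS summary statistics plus an LD reference panel** or from
**individual-level genotypes**. The L1 penalty, however, is
non-differentiable, which rules out plain gradient-based minimization.

This package replaces each absolute value with its Nesterov smoothing under
the entropy prox-function,

```
f_μ(z) = μ log(½ e^(−z/μ) + ½ e^(z/μ)),     f_μ'(z) = tanh(z/μ),
```

giving a strictly convex objective `L_μ` with a closed-form gradient that a
quasi-Newton method minimizes directly, together with the a-priori guarantee

```
0 ≤ L(β) − L_μ(β) ≤ 2 λ p μ log 2        for every β.
```

The audience is statistical geneticists who want a differentiable,
reference-panel-compatible penalized PRS/IRM fit with explicit accuracy
control, plus a self-contained simulator to validate the whole pipeline
without access to restricted genotype data.

## Worked example

Simulate a cohort (LD-structured genotypes, 10 causal variants, h² = 0.5,
two covariates), fit an integrated risk model on two thirds of the samples
and evaluate on the held-out third:

```r
library(slassosum)

cfg   <- simulation_config(seed = 42)          # n = 750, p = 200 by default
sim   <- simulate_genotypes(cfg)
ph    <- simulate_phenotype(sim$panel, cfg)
split <- train_validation_split(cfg$n, prop_train = 2/3, seed = 42)

fit <- irm(sim$panel$dosages[split$train, ], ph$y[split$train],
           ph$Z[split$train, ])
fit
#> Integrated risk model (individual-level mode, continuous outcome)
#>   200 variants, 2 covariate(s)
#>   lambda = 0.125, s = 0.5, mu = 0.1; smoothing deviation bound = 3.466
#>   optimizer converged (gradient sup-norm 1.41e-07)

yhat <- predict(fit, sim$panel$dosages[split$validation, ],
                ph$Z[split$validation, ])
evaluate_predictions(ph$y[split$validation], yhat, "continuous")
#> Evaluation on 250 held-out samples (continuous outcome)
#>   mean absolute residual: 0.6255
#>   correlation:            0.6428
```

The printed *smoothing deviation bound* is `2λpμ log 2 = 3.466` objective
units for this `(λ = 2⁻³, p = 200, μ = 0.1)`: the guaranteed maximum gap
between the smoothed objective being minimized and the exact Lassosum
objective. The mean absolute residual and the correlation between predicted
and true outcomes are the held-out accuracy; with h² = 0.5 and covariate
effects (0.3, 0.2) the best achievable correlation here is about 0.8, of
which the penalized fit recovers 0.64 at these sample sizes.
`summary(fit)` lists covariate coefficients and the largest SNP effects on
the correlation scale.

The same model fits from summary statistics alone:

```r
stats <- make_summary_stats(sim$panel, ph$y)      # or read_summary_stats()
fit2  <- irm_from_summary_stats(stats, sim$ref_panel)
```

A four-stage command-line workflow (`simulate`, `fit`, `predict`,
`evaluate`) over TSV/JSON artifacts — including PLINK bed/bim/fam input —
is available through `scripts/slassosum`; see `?run_cli`.

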