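---
title: "Smoothed Lassosum: model, smoothing machinery and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Smoothed Lassosum: model, smoothing machinery and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slassosum)
```

## The model

A polygenic risk score (PRS) predicts an outcome $y$ from allele dosages
$X \in \mathbb{R}^{n \times p}$; an integrated risk model (IRM) adds
epidemiological covariates $Z$ (age, sex, ...). The Lassosum reformulation
of the Lasso objective $\|y - X\beta\|^2 + 2\lambda\|\beta\|_1$ is

$$
L(\beta) = y^\top y + (1-s)\,\beta^\top X_r^\top X_r \beta
  - 2\beta^\top r + s\,\beta^\top \beta + 2\lambda \|\beta\|_1,
$$

where $r = X^\top y$ collects the SNP-wise correlations of the (standardized)
variants with the outcome, $X_r$ is whatever genotype source supplies the
linkage-disequilibrium (LD) structure $X_r^\top X_r$, and $s \in [0,1]$ mixes
in a ridge term that guarantees a unique solution even when the LD matrix is
rank-deficient. The decisive practical property is that $L$ depends on the
data only through $r$, $X_r$ and the scalar $y^\top y$: GWAS summary
statistics plus any LD reference panel are enough to fit it — no
individual-level outcome data needed. With individual-level data one simply
sets $X_r = X$ and $r = X^\top y$.

`lassosum_problem()` holds these pieces. The quadratic term is always
evaluated as $\|X_r \beta\|^2$ (or through a user-supplied operator
$v \mapsto X_r^\top(X_r v)$), never by materializing the $p \times p$ LD
matrix. Because $y^\top y$ only shifts the objective by a constant, it is set
to 0 in summary-statistics mode where it is unknown; the minimizer is
unaffected, and a test asserts exactly that.

## Nesterov smoothing with the entropy prox-function

The L1 penalty is the only non-differentiable part of $L$. Each absolute
value is a two-piece affine maximum, $|z| = \max\{-z, z\}$, and a
piecewise-affine convex function $f(z) = \max_i (A[z,1]^\top)_i$ admits the
Nesterov smoothing $f_\mu(z) = \max_{w \in Q_k} \langle A[z,1]^\top, w\rangle
- \mu\rho(w)$ over the unit simplex. Choosing the entropy prox-function for
$\rho$ gives the closed form

$$
f_\mu(z) = \mu \log\Big(\tfrac1k \sum_{i=1}^k e^{(A[z,1]^\top)_i/\mu}\Big),
\qquad 0 \le f(z) - f_\mu(z) \le \mu \log k .
$$

Specialized to the absolute value ($k = 2$, $A = \bigl(\begin{smallmatrix}
-1 & 0\\ 1 & 0\end{smallmatrix}\bigr)$):

$$
f_\mu(z) = \mu \log\!\Big(\tfrac12 e^{-z/\mu} + \tfrac12 e^{z/\mu}\Big),
\qquad
f_\mu'(z) = \frac{e^{z/\mu} - e^{-z/\mu}}{e^{z/\mu} + e^{-z/\mu}}
  = \tanh(z/\mu).
$$

Substituting $f_\mu$ for $|\cdot|$ in $L$ yields the smoothed objective
$L_\mu$ (`smoothed_objective()`), which is strictly convex for $s > 0$,
everywhere differentiable with the closed-form gradient

$$
\nabla L_\mu(\beta) = 2(1-s)\,X_r^\top X_r \beta - 2r + 2s\beta
 + 2\lambda \tanh(\beta/\mu),
$$

and uniformly within $2\lambda p\mu\log 2$ of the exact objective
(`deviation_bound()`). That bound transfers to the minimizer: the exact
objective evaluated at the smoothed minimizer exceeds the exact optimum by
at most the same amount, so $\mu$ is a user-controlled accuracy knob.

### Numerical form

Evaluated literally, $e^{z/\mu}$ overflows once $|z|/\mu \gtrsim 700$ — at
$\mu = 0.1$ that is $|z| = 70$, well inside the range the optimizer visits
on unscaled problems. All smoothing code therefore uses folded forms:
`smooth_abs()` computes $|z| + \mu\log\big((1 + e^{-2|z|/\mu})/2\big)$ (the
exponent is never positive), the generic `entropy_smooth()` uses a shifted
log-sum-exp, and the derivative is `tanh(z/mu)`, which saturates instead of
overflowing. At $\mu = 0$ the smoothed forms are undefined as written;
`entropy_smooth()` dispatches to the exact `piecewise_max()` there, matching
the $\mu \to 0$ limit.

## Fitting

`fit_smoothed_lassosum()` minimizes $L_\mu$ with a limited-memory
quasi-Newton line search (`stats::optim`, `method = "L-BFGS-B"`) driven by
the analytic gradient. Any line-search quasi-Newton scheme using only
objective and gradient calls would do; the limited-memory variant keeps the
cost at $O(p)$ memory for large variant counts. Defaults:

* `lambda = 2^-3` — keeps the estimate neither dense (too-small $\lambda$)
  nor identically zero (too-large $\lambda$) on correlation-scale inputs;
* `s = 0.5` — the standard Lassosum stability recommendation;
* `mu = 0.1` — smoothing error $2\lambda p \mu \log 2 \approx 0.017 p$
  units of objective, while keeping the gradient well-conditioned
  ($\tanh(\cdot/\mu)$ has curvature $\le 1/\mu$);
* `grad_tol = 1e-6` (sup-norm of the gradient, mapped onto L-BFGS-B's
  `pgtol`), `max_iter = 10^4`, start at $\beta_0 = 0$. Strict convexity
  makes the starting point immaterial to the solution (a test fits from two
  starts and checks agreement to $10^{-4}$); zero is cheap and always
  feasible. Exhausting `max_iter` flags the result as unconverged rather
  than raising an error.

The smoothed penalty trades exact zeros for differentiability: minimizers
are dense, with would-be-zero coordinates landing near
$\mu\,\mathrm{artanh}(r_j/\lambda')$ rather than at 0. `sparsify()` restores
sparsity post hoc by zeroing entries below a threshold $\tau$; the package
deliberately leaves $\tau$ to the user since thresholding can cost
predictive accuracy.

## The integrated-risk-model pipeline

`irm()` implements the covariate pipeline: (1) standardize the dosage
columns, (2) regress $y$ on $[1, Z]$ by ordinary least squares and keep the
residuals, (3) form $r$ from the residuals, (4) minimize $L_\mu$ with LD
from the study genotypes, (5) package covariate coefficients, SNP effects
and standardization constants into one object. Predictions on new samples
use the *training* centers/scales (anything else would leak validation
information into the standardization) and compose the covariate and SNP
parts additively.

Two scale conventions needed fixing where the underlying method is silent:

* **Column standardization.** Columns are centered and scaled to unit
  Euclidean norm (not unit variance), so `diag(crossprod(X_std)) = 1` and
  $X_{std}^\top u$ is a genuine correlation vector for unit-norm $u$. This
  makes $r$ and the LD matrix commensurable as correlations.
* **Residual scale.** Covariate residuals are divided by their norm before
  forming $r$, and the stored norm multiplies the SNP contribution back at
  prediction time. Without this, $r$ entries scale with $\|y\|$ and a fixed
  $\lambda = 2^{-3}$ penalizes completely different geometry in the two
  input modes; with it, $r \in [-1,1]$ in individual-level mode and the
  summary-statistics and individual-level paths fit on the same scale.
  Residual-based $r$ after covariate regression is *not* guaranteed to stay
  in $(-1,1)$ in general; `residual_correlations()` counts and warns about
  such entries but proceeds, since no principled transformation exists.

Binary outcomes are residualized by the same plain linear regression — the
predictions are real-valued risk scores, not probabilities. This is
adequate because the reported AUC is rank-based and invariant to any
monotone calibration. AUC uses the Mann–Whitney convention (ties count one
half, computed via midranks); the other metrics are the mean of absolute
residuals $\tfrac1n\sum_i |y_i - \hat y_i|$ and the Pearson correlation
between predicted and true outcomes, with a constant prediction vector
reported as `NA` correlation rather than an error. A covariate-only
baseline needs no extra code: it is `irm()`'s own pipeline with the SNP
part zeroed (or an over-penalized fit).

In summary-statistics mode (`irm_from_summary_stats()`), marginal GWAS
effects are first aligned to the reference panel's counted allele
(`harmonize()`: sign-flip on swapped alleles, drop strand-ambiguous A/T and
C/G pairs and allele-set mismatches), then converted to correlations by the
OLS identity $r = t/\sqrt{n - 2 + t^2}$ with $t = \beta/\mathrm{se}$
(`beta_to_correlation()`). The conversion is exact for simple linear
regression — a test confirms it reproduces the empirical Pearson
correlation to $10^{-6}$ on simulated marginal regressions — but it is a
choice, recorded in the fit metadata, since summary-statistics producers do
not document a canonical conversion.

## The synthetic cohort generator

`simulate_genotypes()` draws, per sample, two latent Gaussian haplotype
vectors with within-block AR(1) correlation (`ld_rho^|i-j|` inside blocks
of `block_size` adjacent variants, independence across blocks) and
thresholds each at the allele-frequency quantile $\Phi^{-1}(1-\mathrm{maf})$;
the dosage is the count of exceedances, so the counted allele has the drawn
frequency and adjacent dosages show tetrachoric-attenuated correlation (a
test checks the attenuation against numeric integration of the bivariate
normal orthant probability). `simulate_phenotype()` places `n_causal`
equal-magnitude random-sign effects (Gaussian magnitudes by flag) on the
variance-standardized dosages, rescales them so the realized genetic
variance equals `h2`, adds standard-normal covariates and Gaussian noise to
a total variance of 1, and for binary outcomes thresholds the liability at
the prevalence quantile. `make_summary_stats()` then emulates a GWAS by
per-variant simple regression.

Defaults (`n = 750`, `n_ref = 250`, `p = 200`, `maf ~ U(0.05, 0.5)`,
`ld_rho = 0.5` in blocks of 10, 10 causal variants, `h2 = 0.5`, covariate
effects (0.3, 0.2), prevalence 0.2) are sized so that a desk-scale run
exercises every pathway: appreciable LD within blocks, per-causal-variant
signals (marginal correlation $\approx 0.22$) clearly above the null scale
$1/\sqrt{n}$, yet nontrivial noise. What the generator does **not**
emulate: realistic human LD maps and recombination structure, allele
frequency/effect-size coupling, population stratification, relatedness,
genotyping error and imputation uncertainty. Passing tests therefore
demonstrate the estimator's internal correctness and its behavior under
idealized LD, not performance on real biobank data.

## Evaluation protocols used by the tests and the acceptance script

* **Train/validation splits** are uniform random row subsets
  (`train_validation_split()`), reproducible from one seed; the
  mean-absolute-residual curve is checked to decrease (averaged over
  seeds) as the training proportion grows.
* **Summary-vs-individual comparison.** The two input modes are compared on
  a covariate-free simulation: covariates have no summary-statistics
  pathway, so including them would depress the summary-mode correlation for
  reasons unrelated to the estimator. The GWAS half and the LD reference
  are equally sized (500 training samples, 500 reference samples, 250
  validation samples): the reference panel is meant to *match* the study
  LD, and a much smaller panel measures LD-estimation noise instead of the
  method. Under this protocol the summary path retains at least 95% of the
  individual-level held-out correlation.
* **Exact-optimum oracles.** Where tests need the unsmoothed Lassosum
  optimum they compute it independently — coordinate descent with
  soft-thresholding at $p \le 3$, dense grid search at $p = 1$, the ridge
  normal equations at $\lambda = 0$, and glmnet as an external cross-check
  of the $s = 0$ classic-Lasso case — never the package's own optimizer.
* **Problem sizes.** Tests run at $n \le 5000$, $p \le 300$ (one
  tetrachoric check uses $n = 5000$, the variance-decomposition check
  $n = 10^4$); the acceptance script's simulations use $n \le 1000$,
  $p = 200$. These sizes put every Monte-Carlo assertion several standard
  errors clear of its threshold while keeping the whole suite in the
  minutes range.

## Known limitations

* Dense minimizers are intrinsic to smoothing; variable selection requires
  post-hoc thresholding with an unprincipled $\tau$.
* Residual-based $r$ can leave $(-1,1)$; the package warns and proceeds, as
  no transformation restoring the guarantee is available.
* $\lambda$, $s$, $\mu$ are fixed, not cross-validated — matching the
  intended use where they are chosen once per analysis; there is no
  $\lambda$-path.
* The LD quadratic uses the full reference matrix product; block-windowed
  LD approximations and shrinkage LD estimators are out of scope.
* The PLINK reader supports the v1.9 two-bit bed format (SNP-major) only;
  VCF/BGEN inputs and genome-build liftover are out of scope.
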