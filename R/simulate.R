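# Synthetic cohort generator: LD-structured dosages, sparse causal effects,
# covariates, continuous or liability-threshold binary outcomes, and
# marginal-regression summary statistics.

#' Configuration of a synthetic genotype--phenotype cohort
#'
#' The generator emulates the inputs of a polygenic-risk-score analysis at
#' desk scale. Genotypes are built from latent Gaussian haplotypes with
#' block-wise AR(1) correlation (`ld_rho^|i-j|` within blocks of
#' `block_size` adjacent variants, independence across blocks), thresholded
#' at the minor-allele-frequency quantile so each variant's counted-allele
#' frequency is drawn uniformly from `maf_range`. Phenotypes follow the
#' linear model `y = X_std beta + Z gamma + eps` with `n_causal` causal
#' variants, genetic variance `h2`, independent standard-normal covariates
#' with effects `covariate_effects`, and independent Gaussian noise
#' `eps ~ N(0, sigma^2 I)` with `sigma^2 = 1 - h2 - sum(gamma^2)` so the
#' total outcome variance is 1. Binary outcomes threshold the continuous
#' liability at the `1 - prevalence` quantile.
#'
#' @param n study sample count.
#' @param n_ref reference-panel sample count (drawn independently from the
#'   same LD process).
#' @param p variant count.
#' @param maf_range minor-allele-frequency interval within (0, 0.5].
#' @param ld_rho adjacent-variant latent correlation within a block, in
#'   `[0, 1)`.
#' @param block_size number of adjacent variants per LD block.
#' @param n_causal number of causal variants (at most `p`).
#' @param h2 target genetic variance fraction in `[0, 1]`; 1 (with no
#'   covariates) is the noise-free limit.
#' @param covariate_effects numeric vector of covariate effects (possibly
#'   empty).
#' @param outcome_type `"continuous"` or `"binary"`.
#' @param prevalence case fraction for binary outcomes.
#' @param effect_dist `"fixed"` (equal magnitudes, random signs) or
#'   `"gaussian"` causal effect sizes.
#' @param seed integer seed; every draw is reproducible from it.
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(n = 750, n_ref = 250, p = 200,
                              maf_range = c(0.05, 0.5), ld_rho = 0.5,
                              block_size = 10, n_causal = 10, h2 = 0.5,
                              covariate_effects = c(0.3, 0.2),
                              outcome_type = c("continuous", "binary"),
                              prevalence = 0.2,
                              effect_dist = c("fixed", "gaussian"),
                              seed = 42L) {
  outcome_type <- match.arg(outcome_type)
  effect_dist <- match.arg(effect_dist)
  if (n < 2 || n_ref < 2 || p < 1) stop("'n', 'n_ref' and 'p' must be >= 2, 2, 1")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("'maf_range' must be an interval within (0, 0.5]")
  if (ld_rho < 0 || ld_rho >= 1) stop("'ld_rho' must lie in [0, 1)")
  if (block_size < 1) stop("'block_size' must be positive")
  if (n_causal < 0 || n_causal > p) stop("'n_causal' must lie in [0, p]")
  if (h2 < 0 || h2 > 1) stop("'h2' must lie in [0, 1]")
  if (h2 > 0 && n_causal == 0) stop("h2 > 0 requires at least one causal variant")
  if (prevalence <= 0 || prevalence >= 1) stop("'prevalence' must lie in (0, 1)")
  if (h2 + sum(covariate_effects^2) > 1)
    stop(sprintf(
      "infeasible variance budget: h2 = %g plus covariate variance %g exceeds 1",
      h2, sum(covariate_effects^2)))
  structure(
    list(n = as.integer(n), n_ref = as.integer(n_ref), p = as.integer(p),
         maf_range = maf_range, ld_rho = ld_rho,
         block_size = as.integer(block_size), n_causal = as.integer(n_causal),
         h2 = h2, covariate_effects = as.numeric(covariate_effects),
         outcome_type = outcome_type, prevalence = prevalence,
         effect_dist = effect_dist, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# latent haplotype field: n x p standard normal with AR(1) blocks
ar1_block_latents <- function(n, p, rho, block_size) {
  Z <- matrix(stats::rnorm(n * p), n, p)
  if (rho == 0 || p == 1) return(Z)
  sd_innov <- sqrt(1 - rho^2)
  for (j in 2:p) {
    if ((j - 1) %% block_size == 0) next  # new block: independent start
    Z[, j] <- rho * Z[, j - 1] + sd_innov * Z[, j]
  }
  Z
}

non_ambiguous_pairs <- rbind(
  c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
  c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G"))

#' Simulate LD-structured genotype panels
#'
#' Draws, per sample, two latent Gaussian haplotype vectors with block-AR(1)
#' correlation and thresholds each at `qnorm(1 - maf_j)`; the dosage is the
#' number of haplotypes exceeding the threshold, so the counted allele (A1)
#' has frequency `maf_j`. A second, independent panel of `n_ref` samples is
#' generated from the same process to serve as the LD reference. Allele
#' labels are drawn from the non-strand-ambiguous pairs only.
#'
#' @param cfg a [simulation_config()].
#' @return A list with `panel` (the study [genotype_panel()]), `ref_panel`
#'   (the reference panel), and `maf` (the per-variant frequencies used).
#' @export
simulate_genotypes <- function(cfg) {
  set.seed(cfg$seed)
  maf <- stats::runif(cfg$p, cfg$maf_range[1], cfg$maf_range[2])
  thr <- stats::qnorm(1 - maf)
  pair_idx <- sample.int(nrow(non_ambiguous_pairs), cfg$p, replace = TRUE)
  variants <- data.frame(
    chrom = "1",
    pos = seq_len(cfg$p) * 1000L,
    a1 = non_ambiguous_pairs[pair_idx, 1],
    a2 = non_ambiguous_pairs[pair_idx, 2],
    stringsAsFactors = FALSE
  )
  draw <- function(nn, prefix) {
    h1 <- ar1_block_latents(nn, cfg$p, cfg$ld_rho, cfg$block_size)
    h2 <- ar1_block_latents(nn, cfg$p, cfg$ld_rho, cfg$block_size)
    dos <- sweep(h1, 2, thr, ">") + sweep(h2, 2, thr, ">")
    genotype_panel(dos, variants,
                   sample_ids = sprintf("%s%04d", prefix, seq_len(nn)))
  }
  panel <- draw(cfg$n, "ID")
  ref_panel <- draw(cfg$n_ref, "REF")
  list(panel = panel, ref_panel = ref_panel, maf = maf)
}

#' Simulate phenotypes, covariates and true effects for a panel
#'
#' Causal variants are a random subset of size `n_causal`; their effects on
#' the variance-standardized dosages have equal magnitude with random signs
#' (or Gaussian magnitudes), rescaled so the realized genetic variance in
#' this sample equals `h2`. Covariates are independent standard normal with
#' the configured effects, and the residual noise variance completes the
#' unit variance budget. For binary outcomes the continuous liability is
#' thresholded at `qnorm(1 - prevalence)`.
#'
#' @param panel a [genotype_panel()] from [simulate_genotypes()].
#' @param cfg the [simulation_config()] used to generate it.
#' @return A list with `y` (outcome), `Z` (covariate matrix, 0 columns when
#'   no covariate effects are configured), `true_beta` (p-vector of causal
#'   effects on the variance-standardized dosage scale), `true_gamma`,
#'   `causal_idx`, and `liability` (for binary outcomes).
#' @export
simulate_phenotype <- function(panel, cfg) {
  set.seed(cfg$seed + 1L)
  n <- nrow(panel$dosages)
  p <- ncol(panel$dosages)
  X_std <- scale(panel$dosages)  # unit-variance scale for variance bookkeeping
  true_beta <- numeric(p)
  causal_idx <- integer(0)
  g <- numeric(n)
  if (cfg$h2 > 0 && cfg$n_causal > 0) {
    causal_idx <- sort(sample.int(p, cfg$n_causal))
    raw <- switch(cfg$effect_dist,
      fixed = sample(c(-1, 1), cfg$n_causal, replace = TRUE),
      gaussian = stats::rnorm(cfg$n_causal))
    true_beta[causal_idx] <- raw
    g <- drop(X_std %*% true_beta)
    # rescale so the realized genetic variance equals h2 exactly
    fac <- sqrt(cfg$h2 / stats::var(g))
    true_beta <- true_beta * fac
    g <- g * fac
  }
  c_cov <- length(cfg$covariate_effects)
  Z <- matrix(stats::rnorm(n * c_cov), n, c_cov,
              dimnames = list(NULL, if (c_cov) sprintf("Z%d", seq_len(c_cov))))
  true_gamma <- cfg$covariate_effects
  sigma2 <- max(0, 1 - cfg$h2 - sum(true_gamma^2))  # 0 in the noise-free limit
  liability <- g + (if (c_cov) drop(Z %*% true_gamma) else 0) +
    stats::rnorm(n, sd = sqrt(sigma2))
  y <- if (cfg$outcome_type == "binary")
    as.integer(liability > stats::qnorm(1 - cfg$prevalence))
  else liability
  list(y = y, Z = Z, true_beta = true_beta, true_gamma = true_gamma,
       causal_idx = causal_idx,
       liability = if (cfg$outcome_type == "binary") liability else NULL)
}

#' Marginal-regression summary statistics for a panel
#'
#' Regresses the outcome on each variant's raw dosage separately (simple
#' linear regression with intercept) and reports, per variant, the slope
#' ("Beta" for the counted allele A1), its standard error, the two-sided
#' t-test p-value and the sample size — the standard GWAS summary format.
#' Constant variants cannot be tested and are dropped with a warning.
#'
#' @param panel a [genotype_panel()].
#' @param y numeric outcome vector of length `nrow(panel$dosages)`.
#' @return A `summary_stats` table (see [read_summary_stats()]).
#' @export
make_summary_stats <- function(panel, y) {
  X <- panel$dosages
  n <- nrow(X)
  if (length(y) != n) stop("'y' and the panel disagree on the sample count")
  xm <- colMeans(X)
  Sxx <- colSums(X^2) - n * xm^2
  keep <- Sxx > 0
  if (!all(keep))
    warning(sprintf("dropped %d constant variant(s)", sum(!keep)))
  X <- X[, keep, drop = FALSE]
  xm <- xm[keep]; Sxx <- Sxx[keep]
  ym <- mean(y)
  Sxy <- drop(crossprod(X, y)) - n * xm * ym
  Syy <- sum(y^2) - n * ym^2
  b <- Sxy / Sxx
  rss <- pmax(Syy - b * Sxy, 0)
  se <- sqrt(rss / (n - 2) / Sxx)
  tstat <- b / se
  pval <- 2 * stats::pt(-abs(tstat), df = n - 2)
  v <- panel$variants[keep, , drop = FALSE]
  df <- data.frame(
    chrom = v$chrom, pos = v$pos,
    effect_allele = v$a1, other_allele = v$a2,
    beta = b, se = se,
    pvalue = pmax(pval, .Machine$double.xmin),  # keep within (0, 1]
    n_gwas = n, stringsAsFactors = FALSE
  )
  rownames(df) <- NULL
  class(df) <- c("summary_stats", "data.frame")
  df
}

#' Reproducible train/validation split
#'
#' Selects `round(prop_train * n)` sample indices uniformly at random for
#' training; the remainder form the validation set.
#'
#' @param n sample count.
#' @param prop_train training proportion in (0, 1).
#' @param seed optional integer seed.
#' @return A list with integer vectors `train` and `validation`.
#' @export
train_validation_split <- function(n, prop_train, seed = NULL) {
  if (prop_train <= 0 || prop_train >= 1) stop("'prop_train' must lie in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  n_train <- max(1L, min(n - 1L, round(prop_train * n)))
  train <- sort(sample.int(n, n_train))
  list(train = train, validation = setdiff(seq_len(n), train))
}
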