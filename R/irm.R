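# Integrated risk models: covariate residualization, residual correlations,
# the end-to-end penalized fit, prediction and evaluation.

#' Ordinary least-squares residualization of epidemiological covariates
#'
#' Regresses the outcome on the covariates (with intercept) by ordinary
#' least squares and returns the coefficients and residuals. With no
#' covariates this reduces to centering the outcome. The residuals are
#' orthogonal to every covariate column and sum to zero; the penalized SNP
#' model is subsequently fit to them.
#'
#' @param Z numeric covariate matrix (`n` samples x `c` covariates; `c` may
#'   be 0) or `NULL`.
#' @param y numeric outcome vector; binary outcomes are residualized by the
#'   same linear (not logistic) regression and the downstream predictions
#'   are real-valued risk scores.
#' @return A list with `gamma_hat` (named coefficients, intercept first)
#'   and `residuals`.
#' @export
regress_covariates <- function(Z, y) {
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(Z)) Z <- matrix(numeric(0), n, 0)
  Z <- as.matrix(Z)
  if (nrow(Z) != n) stop("'Z' and 'y' disagree on the sample count")
  if (is.null(colnames(Z)) && ncol(Z) > 0)
    colnames(Z) <- sprintf("Z%d", seq_len(ncol(Z)))
  D <- cbind("(Intercept)" = 1, Z)
  if (n <= ncol(D)) stop("need more samples than covariates plus intercept")
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    bad <- colnames(D)[qrD$pivot[(qrD$rank + 1):ncol(D)]]
    stop("covariate matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  gamma_hat <- qr.coef(qrD, y)
  res <- y - drop(D %*% gamma_hat)
  list(gamma_hat = gamma_hat, residuals = res)
}

#' SNP-wise correlations of standardized dosages with a residual vector
#'
#' Computes `r = crossprod(X_std, residuals)`. When the residual vector has
#' unit Euclidean norm these are per-variant correlations in `[-1, 1]`;
#' residuals of a covariate regression carry no such guarantee, so entries
#' outside `(-1, 1)` are counted and reported in a warning rather than
#' treated as an error.
#'
#' @param X_std standardized dosage matrix (see [standardize_dosages()]).
#' @param residuals numeric vector.
#' @return The numeric `p`-vector `r`.
#' @export
residual_correlations <- function(X_std, residuals) {
  X_std <- as.matrix(X_std)
  if (nrow(X_std) != length(residuals))
    stop("'X_std' and 'residuals' disagree on the sample count")
  r <- drop(crossprod(X_std, residuals))
  n_out <- sum(abs(r) >= 1)
  if (n_out > 0)
    warning(sprintf("%d correlation entr%s outside (-1, 1)", n_out,
                    if (n_out == 1) "y lies" else "ies lie"))
  r
}

#' Fit an integrated risk model from individual-level data
#'
#' The full pipeline: standardize the dosage matrix, residualize the
#' epidemiological covariates out of the outcome by ordinary least squares,
#' rescale the residuals to unit norm so the SNP-wise correlations
#' `r = crossprod(X_std, u)` live on the correlation scale (the scale the
#' fixed penalty is calibrated for), and minimize the smoothed Lassosum
#' objective with LD taken from the study genotypes themselves. The
#' returned object predicts on new samples via
#' `yhat = cbind(1, Z_new) %*% gamma_hat + s_r * X_new_std %*% beta_hat`,
#' where `s_r` is the stored residual norm and `X_new_std` uses the
#' training standardization constants.
#'
#' @param X dosage matrix (`n` samples x `p` variants) or a
#'   [genotype_panel()].
#' @param y outcome vector: continuous, or binary coded 0/1.
#' @param Z optional covariate matrix.
#' @param cfg a [fit_config()].
#' @param variant_ids optional variant identifiers (taken from the panel or
#'   column names when available).
#' @return An object of class `"irm"`; see [predict.irm()],
#'   [evaluate_predictions()].
#' @examples
#' cfg <- simulation_config(n = 200, p = 40, n_causal = 4, seed = 7)
#' sim <- simulate_genotypes(cfg)
#' ph <- simulate_phenotype(sim$panel, cfg)
#' fit <- irm(sim$panel, ph$y, ph$Z)
#' print(fit)
#' @export
irm <- function(X, y, Z = NULL, cfg = fit_config(), variant_ids = NULL) {
  if (inherits(X, "genotype_panel")) {
    if (is.null(variant_ids)) variant_ids <- X$variants$id
    X <- X$dosages
  }
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("[standardize] 'X' and 'y' disagree on the sample count")
  if (is.null(variant_ids))
    variant_ids <- colnames(X) %||% sprintf("V%d", seq_len(ncol(X)))
  outcome_type <- if (all(y %in% c(0, 1))) "binary" else "continuous"

  std <- tryCatch(standardize_dosages(X),
                  error = function(e) stop("[standardize] ", conditionMessage(e)))
  cov_fit <- tryCatch(regress_covariates(Z, y),
                      error = function(e) stop("[residualize] ", conditionMessage(e)))
  u <- cov_fit$residuals
  resid_scale <- sqrt(sum(u^2))
  if (resid_scale == 0)
    stop("[residualize] residuals are identically zero; nothing left for the SNP model")
  r <- residual_correlations(std$X_std, u / resid_scale)
  prob <- lassosum_problem(std$X_std, r, yty = 1, s = cfg$s, lambda = cfg$lambda)
  fit <- tryCatch(fit_smoothed_lassosum(prob, cfg),
                  error = function(e) stop("[fit] ", conditionMessage(e)))

  structure(
    list(gamma_hat = cov_fit$gamma_hat,
         beta_hat = stats::setNames(fit$beta_hat, variant_ids[std$kept]),
         resid_scale = resid_scale,
         standardization = list(centers = std$centers, scales = std$scales),
         variant_ids = variant_ids[std$kept],
         covariate_names = names(cov_fit$gamma_hat)[-1],
         outcome_type = outcome_type,
         mode = "individual",
         fit = fit, cfg = cfg,
         deviation_bound = deviation_bound(cfg$lambda, prob$p, cfg$mu)),
    class = "irm"
  )
}

#' Fit a polygenic risk score from summary statistics and a reference panel
#'
#' The summary-statistics input path: marginal GWAS effects are harmonized
#' to the reference panel's allele orientation ([harmonize()]), converted
#' to per-variant outcome correlations ([beta_to_correlation()]), and the
#' smoothed Lassosum objective is minimized with LD estimated from the
#' standardized reference panel. No covariates or outcome are needed; the
#' resulting object predicts a real-valued risk score
#' `X_new_std %*% beta_hat` (reference-panel standardization constants).
#'
#' @param stats a `summary_stats` table with an `n_gwas` column (or supply
#'   `n_gwas`).
#' @param ref_panel a [genotype_panel()] supplying LD.
#' @param n_gwas GWAS sample size; overrides the table's column.
#' @param cfg a [fit_config()].
#' @return An object of class `"irm"` with an intercept-only covariate part.
#' @export
irm_from_summary_stats <- function(stats, ref_panel, n_gwas = NULL,
                                   cfg = fit_config()) {
  harm <- harmonize(stats, ref_panel)
  st <- harm$stats
  if (is.null(n_gwas)) {
    if (is.null(st$n_gwas) || anyNA(st$n_gwas))
      stop("'n_gwas' is required when the table has no complete n_gwas column")
    n_gwas <- st$n_gwas
  }
  r <- beta_to_correlation(st$beta, st$se, n_gwas)
  std <- standardize_dosages(ref_panel$dosages[, harm$index, drop = FALSE])
  r <- r[std$kept]
  variant_ids <- ref_panel$variants$id[harm$index][std$kept]
  prob <- lassosum_problem(std$X_std, r, yty = 0, s = cfg$s, lambda = cfg$lambda)
  fit <- fit_smoothed_lassosum(prob, cfg)
  structure(
    list(gamma_hat = c("(Intercept)" = 0),
         beta_hat = stats::setNames(fit$beta_hat, variant_ids),
         resid_scale = 1,
         standardization = list(centers = std$centers, scales = std$scales),
         variant_ids = variant_ids,
         covariate_names = character(0),
         outcome_type = "score",
         mode = "summary",
         fit = fit, cfg = cfg,
         deviation_bound = deviation_bound(cfg$lambda, prob$p, cfg$mu)),
    class = "irm"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict outcomes or risk scores from a fitted integrated risk model
#'
#' Standardizes the new dosages with the training constants and returns
#' `cbind(1, Z_new) %*% gamma_hat + resid_scale * X_new_std %*% beta_hat`.
#' The variant set (and order) must match the fit; covariates must be
#' supplied whenever the model was fit with covariates.
#'
#' @param object an `"irm"` fit.
#' @param X_new dosage matrix or [genotype_panel()] for the new samples.
#' @param Z_new covariate matrix for the new samples, if the fit used any.
#' @param ... unused.
#' @return Numeric vector of predicted outcomes (continuous), risk scores
#'   (binary/score), one per new sample.
#' @export
predict.irm <- function(object, X_new, Z_new = NULL, ...) {
  ids_new <- NULL
  if (inherits(X_new, "genotype_panel")) {
    ids_new <- X_new$variants$id
    X_new <- X_new$dosages
  } else {
    ids_new <- colnames(X_new)
  }
  X_new <- as.matrix(X_new)
  if (!is.null(ids_new)) {
    if (!all(object$variant_ids %in% ids_new)) {
      miss <- setdiff(object$variant_ids, ids_new)
      stop("new data lack fitted variant(s): ",
           paste(utils::head(miss, 5), collapse = ", "),
           if (length(miss) > 5) sprintf(" (and %d more)", length(miss) - 5))
    }
    X_new <- X_new[, object$variant_ids, drop = FALSE]
  } else if (ncol(X_new) != length(object$beta_hat)) {
    stop(sprintf("new data have %d variants but the fit has %d",
                 ncol(X_new), length(object$beta_hat)))
  }
  Xs <- sweep(sweep(X_new, 2, object$standardization$centers), 2,
              object$standardization$scales, "/")
  prs <- object$resid_scale * drop(Xs %*% object$beta_hat)
  c_cov <- length(object$covariate_names)
  if (c_cov > 0) {
    if (is.null(Z_new)) stop("the fit uses covariates; supply 'Z_new'")
    Z_new <- as.matrix(Z_new)
    if (ncol(Z_new) != c_cov)
      stop(sprintf("expected %d covariate column(s), got %d", c_cov, ncol(Z_new)))
    drop(cbind(1, Z_new) %*% object$gamma_hat) + prs
  } else {
    object$gamma_hat[[1]] + prs
  }
}

#' @export
coef.irm <- function(object, ...) {
  c(object$gamma_hat, object$resid_scale * object$beta_hat)
}

#' @export
print.irm <- function(x, ...) {
  cat(sprintf("Integrated risk model (%s-level mode, %s outcome)\n",
              if (x$mode == "summary") "summary-statistics" else "individual",
              x$outcome_type))
  cat(sprintf("  %d variants, %d covariate(s)\n",
              length(x$beta_hat), length(x$covariate_names)))
  cat(sprintf("  lambda = %g, s = %g, mu = %g; smoothing deviation bound = %.4g\n",
              x$cfg$lambda, x$cfg$s, x$cfg$mu, x$deviation_bound))
  cat(sprintf("  optimizer %s (gradient sup-norm %.3g)\n",
              if (x$fit$converged) "converged" else "did NOT converge",
              x$fit$grad_norm))
  invisible(x)
}

#' @export
summary.irm <- function(object, tau = 1e-3, ...) {
  b <- object$beta_hat
  out <- list(
    mode = object$mode, outcome_type = object$outcome_type,
    n_variants = length(b),
    n_effective = sum(abs(b) >= tau), tau = tau,
    top_variants = utils::head(b[order(-abs(b))], 10),
    gamma_hat = object$gamma_hat,
    deviation_bound = object$deviation_bound,
    converged = object$fit$converged
  )
  class(out) <- "summary.irm"
  out
}

#' @export
print.summary.irm <- function(x, ...) {
  cat(sprintf("Integrated risk model (%s mode): %d variants, %d with |beta| >= %g\n",
              x$mode, x$n_variants, x$n_effective, x$tau))
  cat("Covariate coefficients:\n")
  print(x$gamma_hat)
  cat("Largest SNP effects (correlation scale):\n")
  print(round(x$top_variants, 5))
  invisible(x)
}

#' Evaluate predictions against held-out outcomes
#'
#' Reports the mean of absolute residuals `mean(abs(y - yhat))`, the
#' Pearson correlation between predicted and true outcomes, and — for
#' binary outcomes only — the AUC, computed by the Mann--Whitney rule (the
#' probability that a random case scores above a random control, ties
#' counted one half). A constant prediction vector has no defined
#' correlation; it is reported as `NA` with a warning.
#'
#' @param y_true observed outcomes (0/1 for binary).
#' @param y_pred predicted outcomes or risk scores.
#' @param outcome_type `"continuous"` or `"binary"`.
#' @return A list of class `"evaluation_report"` with elements
#'   `mean_abs_residuals`, `auc` (`NA` unless binary), `correlation` and
#'   `n_validation`.
#' @examples
#' evaluate_predictions(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1), "binary")
#' @export
evaluate_predictions <- function(y_true, y_pred,
                                 outcome_type = c("continuous", "binary")) {
  outcome_type <- match.arg(outcome_type)
  y_true <- as.numeric(y_true); y_pred <- as.numeric(y_pred)
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  n <- length(y_true)
  mar <- mean(abs(y_true - y_pred))
  if (stats::sd(y_pred) == 0) {
    warning("constant predictions: correlation is undefined")
    corr <- NA_real_
  } else {
    corr <- stats::cor(y_true, y_pred)
  }
  auc <- NA_real_
  if (outcome_type == "binary") {
    if (!all(y_true %in% c(0, 1))) stop("binary outcomes must be coded 0/1")
    n1 <- sum(y_true == 1); n0 <- n - n1
    if (n1 == 0 || n0 == 0) stop("AUC needs both cases and controls")
    # midranks give the ties-as-half Mann-Whitney statistic
    auc <- (sum(rank(y_pred)[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  structure(list(mean_abs_residuals = mar, auc = auc, correlation = corr,
                 n_validation = n, outcome_type = outcome_type),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Evaluation on %d held-out samples (%s outcome)\n",
              x$n_validation, x$outcome_type))
  cat(sprintf("  mean absolute residual: %.4f\n", x$mean_abs_residuals))
  if (!is.na(x$auc)) cat(sprintf("  AUC:                    %.4f\n", x$auc))
  cat(sprintf("  correlation:            %.4f\n", x$correlation))
  invisible(x)
}

#' @rdname evaluate_predictions
#' @param report an `evaluation_report`.
#' @param path output file; format chosen by extension (`.json` or TSV).
#' @export
write_evaluation_report <- function(report, path) {
  vals <- list(mean_abs_residuals = report$mean_abs_residuals,
               auc = report$auc, correlation = report$correlation,
               n_validation = report$n_validation,
               outcome_type = report$outcome_type)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    utils::write.table(
      data.frame(key = names(vals),
                 value = vapply(vals, function(v) as.character(v), "")),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
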