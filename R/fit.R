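# Quasi-Newton minimization of the smoothed Lassosum objective.

#' Fitting configuration for the smoothed Lassosum
#'
#' Default parameter values follow the fixed choices used throughout the
#' integrated-risk-model analyses: \eqn{\lambda = 2^{-3}} (keeps the estimate
#' neither dense nor identically zero), \eqn{s = 0.5} (the recommended
#' Lassosum stability setting) and \eqn{\mu = 0.1}. The optimizer stops when
#' the gradient sup-norm drops below `grad_tol` or after `max_iter`
#' iterations.
#'
#' @param mu positive smoothing parameter.
#' @param lambda non-negative L1 penalty.
#' @param s stability regularizer in `[0, 1]`.
#' @param grad_tol convergence tolerance on the gradient sup-norm.
#' @param max_iter maximum number of quasi-Newton iterations.
#' @param init initial coefficient vector, or `"zeros"`.
#' @return A list of class `"fit_config"`.
#' @export
fit_config <- function(mu = 0.1, lambda = 2^-3, s = 0.5,
                       grad_tol = 1e-6, max_iter = 10000L, init = "zeros") {
  check_mu(mu)
  if (lambda < 0) stop("'lambda' must be non-negative")
  if (s < 0 || s > 1) stop("'s' must lie in [0, 1]")
  if (grad_tol <= 0) stop("'grad_tol' must be positive")
  if (max_iter < 1) stop("'max_iter' must be a positive integer")
  structure(
    list(mu = mu, lambda = lambda, s = s, grad_tol = grad_tol,
         max_iter = as.integer(max_iter), init = init),
    class = "fit_config"
  )
}

#' Minimize the smoothed Lassosum objective
#'
#' Runs a limited-memory quasi-Newton line search (`stats::optim`,
#' `method = "L-BFGS-B"`) on the strictly convex smoothed objective using
#' its closed-form gradient. Strict convexity (for `s > 0`) guarantees a
#' unique minimizer, so the result does not depend on the starting point;
#' the default start is the zero vector. The optimizer path is fully
#' deterministic.
#'
#' @param prob a [lassosum_problem()]; its `s` and `lambda` are overridden
#'   by the configuration so that one problem can be refit under several
#'   penalty settings.
#' @param cfg a [fit_config()].
#' @return An object of class `"slassosum_fit"` with elements `beta_hat`,
#'   `objective_value` (smoothed objective at the solution), `grad_norm`
#'   (gradient sup-norm at the solution), `n_iter`, `converged`, and the
#'   configuration and problem dimensions used.
#' @examples
#' set.seed(1)
#' X <- scale(matrix(rnorm(200), 20, 10))
#' X <- sweep(X, 2, sqrt(colSums(X^2)), "/")
#' y <- rnorm(20); y <- y / sqrt(sum(y^2))
#' prob <- lassosum_problem(X, drop(crossprod(X, y)), yty = 1)
#' fit <- fit_smoothed_lassosum(prob, fit_config())
#' coef(fit)
#' @export
fit_smoothed_lassosum <- function(prob, cfg = fit_config()) {
  if (!inherits(prob, "lassosum_problem")) stop("'prob' must be a lassosum_problem")
  if (!inherits(cfg, "fit_config")) stop("'cfg' must be a fit_config")
  prob$s <- cfg$s
  prob$lambda <- cfg$lambda
  beta0 <- if (identical(cfg$init, "zeros")) numeric(prob$p)
           else check_beta(cfg$init, prob)

  res <- stats::optim(
    par = beta0,
    fn = function(b) smoothed_objective(b, prob, cfg$mu),
    gr = function(b) smoothed_gradient(b, prob, cfg$mu),
    method = "L-BFGS-B",
    control = list(maxit = cfg$max_iter, pgtol = cfg$grad_tol, factr = 1)
  )
  g <- smoothed_gradient(res$par, prob, cfg$mu)
  grad_norm <- max(abs(g))
  structure(
    list(beta_hat = res$par,
         objective_value = res$value,
         grad_norm = grad_norm,
         n_iter = res$counts[["function"]],
         converged = grad_norm <= cfg$grad_tol || res$convergence == 0L,
         message = res$message,
         cfg = cfg, p = prob$p),
    class = "slassosum_fit"
  )
}

#' @export
print.slassosum_fit <- function(x, ...) {
  cat(sprintf("Smoothed Lassosum fit: p = %d variants\n", x$p))
  cat(sprintf("  lambda = %g, s = %g, mu = %g\n",
              x$cfg$lambda, x$cfg$s, x$cfg$mu))
  cat(sprintf("  smoothed objective = %.6g, gradient sup-norm = %.3g\n",
              x$objective_value, x$grad_norm))
  cat(sprintf("  %s after %d objective evaluations\n",
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  cat(sprintf("  nonzero effects after thresholding at 1e-3: %d\n",
              sum(abs(x$beta_hat) >= 1e-3)))
  invisible(x)
}

#' @export
coef.slassosum_fit <- function(object, ...) object$beta_hat

#' Threshold small effects to restore sparsity
#'
#' The smoothed penalty yields dense minimizers: coordinates the exact
#' Lasso would set to zero come out small but nonzero. Sparsity can be
#' restored after fitting by zeroing every entry with \eqn{|\beta_i| < \tau}.
#'
#' @param beta numeric vector of fitted effects.
#' @param tau non-negative threshold.
#' @return `beta` with entries smaller than `tau` in absolute value set to 0.
#' @export
sparsify <- function(beta, tau) {
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau < 0)
    stop("'tau' must be a single non-negative number")
  beta[abs(beta) < tau] <- 0
  beta
}
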