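# The Lassosum objective, its smoothed version, closed-form gradient, and the
# a-priori smoothing deviation bound.

#' Construct a Lassosum problem
#'
#' Bundles everything the (smoothed) Lassosum objective
#' \deqn{L(\beta) = y^T y + (1-s)\,\beta^T X_r^T X_r \beta - 2\beta^T r
#'   + s\,\beta^T\beta + 2\lambda \|\beta\|_1}
#' needs: a linkage-disequilibrium (LD) source \eqn{X_r}, the vector of
#' SNP-wise correlations \eqn{r}, the scalar \eqn{y^T y}, the stability
#' parameter \eqn{s \in [0, 1]} and the penalty \eqn{\lambda \ge 0}. With
#' standardized genotype columns and a unit-norm outcome, \eqn{r = X^T y} is
#' the vector of per-variant correlations with the outcome, which is why a
#' GWAS summary-statistics table (converted by [beta_to_correlation()]) can
#' stand in for individual-level data.
#'
#' The LD source is either a standardized reference dosage matrix (samples by
#' variants; the \eqn{p \times p} matrix \eqn{X_r^T X_r} is never formed) or
#' a function `v |-> t(Xr) %*% (Xr %*% v)` for matrix-free operation.
#'
#' In summary-statistics mode \eqn{y^T y} is unknown; it defaults to 0. It
#' only shifts the objective by a constant and never changes the minimizer.
#'
#' @param ld numeric matrix (`n_ref` samples x `p` variants, standardized so
#'   each column has zero mean and unit Euclidean norm — see
#'   [standardize_dosages()]) or a function implementing
#'   `v |-> t(Xr) %*% (Xr %*% v)`.
#' @param r numeric `p`-vector of SNP-wise correlations with the outcome.
#' @param yty non-negative scalar \eqn{y^T y}; 0 when unknown.
#' @param s stability/uniqueness regularizer in `[0, 1]`. The value 0 gives
#'   the classic Lasso when `ld` holds the study genotypes themselves.
#' @param lambda non-negative L1 penalty \eqn{\lambda}.
#' @param p variant count; required when `ld` is a function, inferred from
#'   `r` otherwise.
#' @return An object of class `"lassosum_problem"`.
#' @export
lassosum_problem <- function(ld, r, yty = 0, s = 0.5, lambda = 2^-3, p = NULL) {
  r <- as.numeric(r)
  if (is.null(p)) p <- length(r)
  if (length(r) != p) stop("length(r) must equal the variant count p")
  if (!all(is.finite(r))) stop("'r' must be finite")
  if (!is.numeric(yty) || length(yty) != 1L || is.na(yty) || yty < 0)
    stop("'yty' must be a single non-negative number")
  if (!is.numeric(s) || length(s) != 1L || is.na(s) || s < 0 || s > 1)
    stop("'s' must lie in [0, 1]")
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) || lambda < 0)
    stop("'lambda' must be a single non-negative number")
  n_ref <- NA_integer_
  if (is.function(ld)) {
    op <- ld
  } else {
    ld <- as.matrix(ld)
    if (ncol(ld) != p)
      stop(sprintf("LD matrix has %d columns but r has length %d", ncol(ld), p))
    n_ref <- nrow(ld)
    op <- NULL
  }
  structure(
    list(ld = if (is.function(ld)) NULL else ld, op = op, r = r, yty = yty,
         s = s, lambda = lambda, p = as.integer(p), n_ref = n_ref),
    class = "lassosum_problem"
  )
}

#' @export
print.lassosum_problem <- function(x, ...) {
  cat(sprintf("Lassosum problem: p = %d variants, lambda = %g, s = %g, yty = %g\n",
              x$p, x$lambda, x$s, x$yty))
  cat(if (is.null(x$op))
    sprintf("  LD from a reference panel of %d samples\n", x$n_ref)
    else "  LD via a matrix-free operator\n")
  invisible(x)
}

check_beta <- function(beta, prob) {
  beta <- as.numeric(beta)
  if (length(beta) != prob$p)
    stop(sprintf("beta has length %d but the problem has p = %d variants",
                 length(beta), prob$p))
  if (!all(is.finite(beta))) stop("'beta' must be finite")
  beta
}

# t(Xr) %*% (Xr %*% beta) without forming the p x p LD matrix
ld_quadform_grad <- function(prob, beta) {
  if (!is.null(prob$op)) prob$op(beta)
  else drop(crossprod(prob$ld, prob$ld %*% beta))
}

# Shared smooth part: yty + (1-s) b'X'Xb - 2 b'r + s b'b, plus the X'Xb
# product for reuse in the gradient.
smooth_part <- function(beta, prob) {
  xtxb <- ld_quadform_grad(prob, beta)
  val <- prob$yty + (1 - prob$s) * sum(beta * xtxb) -
    2 * sum(beta * prob$r) + prob$s * sum(beta^2)
  list(value = val, xtxb = xtxb)
}

#' Lassosum objective, smoothed objective and gradient
#'
#' `lassosum_objective()` evaluates the exact objective with the
#' non-differentiable L1 penalty. `smoothed_objective()` replaces
#' \eqn{2\lambda \|\beta\|_1} with \eqn{2\lambda \sum_i f_\mu(\beta_i)}
#' where \eqn{f_\mu} is the entropy-smoothed absolute value
#' ([smooth_abs()]); the two differ by at most [deviation_bound()]
#' everywhere, with the smoothed value never above the exact one.
#' `smoothed_gradient()` is the closed-form gradient
#' \deqn{\nabla L_\mu(\beta) = 2(1-s) X_r^T X_r \beta - 2r + 2s\beta
#'   + 2\lambda \tanh(\beta/\mu),}
#' computed matrix-free as `t(Xr) %*% (Xr %*% beta)`.
#'
#' @param beta numeric `p`-vector of candidate SNP effects.
#' @param prob a [lassosum_problem()].
#' @param mu positive smoothing parameter.
#' @return A scalar objective value, or a `p`-vector for the gradient.
#' @export
lassosum_objective <- function(beta, prob) {
  beta <- check_beta(beta, prob)
  val <- smooth_part(beta, prob)$value + 2 * prob$lambda * sum(abs(beta))
  if (!is.finite(val)) stop("non-finite Lassosum objective value")
  val
}

#' @rdname lassosum_objective
#' @export
smoothed_objective <- function(beta, prob, mu = 0.1) {
  beta <- check_beta(beta, prob)
  check_mu(mu)
  val <- smooth_part(beta, prob)$value +
    2 * prob$lambda * sum(smooth_abs(beta, mu))
  if (!is.finite(val)) stop("non-finite smoothed Lassosum objective value")
  val
}

#' @rdname lassosum_objective
#' @export
smoothed_gradient <- function(beta, prob, mu = 0.1) {
  beta <- check_beta(beta, prob)
  check_mu(mu)
  g <- 2 * (1 - prob$s) * ld_quadform_grad(prob, beta) - 2 * prob$r +
    2 * prob$s * beta + 2 * prob$lambda * smooth_abs_grad(beta, mu)
  if (!all(is.finite(g))) stop("non-finite smoothed Lassosum gradient")
  g
}

#' A-priori deviation bound between exact and smoothed Lassosum
#'
#' The smoothing error of each absolute value is at most \eqn{\mu \log 2},
#' so the objective deviates from its smoothed version by at most
#' \deqn{0 \le L(\beta) - L_\mu(\beta) \le 2 \lambda p \mu \log 2}
#' uniformly in \eqn{\beta}. This lets the user pick \eqn{\mu} to meet any
#' desired accuracy before fitting.
#'
#' @param lambda non-negative L1 penalty.
#' @param p variant count.
#' @param mu positive smoothing parameter.
#' @return The scalar bound \eqn{2 \lambda p \mu \log 2}.
#' @export
deviation_bound <- function(lambda, p, mu) {
  if (lambda < 0) stop("'lambda' must be non-negative")
  if (p < 1) stop("'p' must be a positive integer")
  check_mu(mu)
  2 * lambda * p * mu * log(2)
}
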