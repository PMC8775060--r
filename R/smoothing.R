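# Nesterov smoothing of piecewise-affine convex functions with the entropy
# prox-function, specialized to the absolute value.

#' Specification of a piecewise-affine convex function for Nesterov smoothing
#'
#' A piecewise-affine convex function \eqn{f(z) = \max_i (A [z, 1]^T)_i} is
#' described by its coefficient matrix `A` (one row per affine piece, constant
#' coefficients in the last column) together with the smoothing parameter
#' `mu`. Smoothing with the entropy prox-function over the unit simplex yields
#' a closed-form smooth approximation (a log-sum-exp; see [entropy_smooth()])
#' that never exceeds `f` and lies within `mu * log(k)` of it everywhere,
#' where `k` is the number of pieces.
#'
#' @param A numeric matrix with `k` rows and `q + 1` columns: affine
#'   coefficients of the `k` pieces of a function of a `q`-vector, constants
#'   in the last column.
#' @param mu non-negative smoothing parameter; `mu = 0` means no smoothing
#'   (the exact piecewise maximum is used).
#' @return An object of class `"smoothing_spec"` with elements `A`, `mu`,
#'   `k` (piece count) and `q` (argument dimension).
#' @seealso [abs_smoothing_spec()] for the absolute-value specialization.
#' @examples
#' sp <- smoothing_spec(rbind(c(-1, 0), c(1, 0)), mu = 0.1)  # |z|, smoothed
#' entropy_smooth(sp, 0.5)
#' @export
smoothing_spec <- function(A, mu = 0.1) {
  A <- as.matrix(A)
  if (!is.numeric(A) || !all(is.finite(A)))
    stop("'A' must be a finite numeric matrix")
  if (ncol(A) < 2L)
    stop("'A' needs at least two columns (affine + constant coefficients)")
  if (!is.numeric(mu) || length(mu) != 1L || is.na(mu) || mu < 0)
    stop("'mu' must be a single non-negative number")
  structure(
    list(A = A, mu = mu, k = nrow(A), q = ncol(A) - 1L),
    class = "smoothing_spec"
  )
}

#' @rdname smoothing_spec
#' @export
abs_smoothing_spec <- function(mu = 0.1) {
  smoothing_spec(rbind(c(-1, 0), c(1, 0)), mu = mu)
}

#' @export
print.smoothing_spec <- function(x, ...) {
  cat(sprintf(
    "Piecewise-affine smoothing spec: k = %d pieces, argument dimension q = %d, mu = %g\n",
    x$k, x$q, x$mu))
  invisible(x)
}

piece_values <- function(spec, z) {
  z <- as.numeric(z)
  if (length(z) != spec$q)
    stop(sprintf("argument has length %d but the spec expects a %d-vector",
                 length(z), spec$q))
  if (!all(is.finite(z))) stop("'z' must be finite")
  drop(spec$A %*% c(z, 1))
}

#' Exact piecewise maximum of a piecewise-affine function
#'
#' Evaluates \eqn{f(z) = \max_i (A [z, 1]^T)_i} exactly.
#'
#' @param spec a [smoothing_spec()].
#' @param z numeric vector of length `spec$q`.
#' @return The scalar maximum over the affine pieces.
#' @export
piecewise_max <- function(spec, z) {
  max(piece_values(spec, z))
}

#' Entropy-prox Nesterov smoothing of a piecewise-affine function
#'
#' For `mu > 0` returns the closed-form smoothed value
#' \deqn{f_\mu(z) = \mu \log\left(\frac{1}{k} \sum_i e^{(A[z,1]^T)_i/\mu}\right),}
#' computed in a log-sum-exp form that is safe for piece values up to
#' \eqn{|a_i|/\mu \approx 10^4} and beyond. For `mu = 0` the exact
#' [piecewise_max()] is returned (the smoothing vanishes in that limit).
#' The result always satisfies
#' \eqn{0 \le f(z) - f_\mu(z) \le \mu \log k}.
#'
#' @inheritParams piecewise_max
#' @return The smoothed scalar value.
#' @export
entropy_smooth <- function(spec, z) {
  mu <- spec$mu
  if (mu == 0) return(piecewise_max(spec, z))
  a <- piece_values(spec, z)
  m <- max(a)
  # mu * (logsumexp(a / mu) - log k)
  m + mu * (log(sum(exp((a - m) / mu))) - log(spec$k))
}

check_mu <- function(mu) {
  if (!is.numeric(mu) || length(mu) != 1L || is.na(mu) || mu <= 0)
    stop("'mu' must be a single positive number")
  mu
}

#' Smoothed absolute value and its derivative
#'
#' The absolute value is the two-piece function
#' \eqn{|z| = \max\{-z, z\}}; its entropy-prox smoothing is
#' \deqn{f_\mu(z) = \mu \log\left(\tfrac12 e^{-z/\mu} + \tfrac12 e^{z/\mu}\right)
#'   = |z| + \mu \log\frac{1 + e^{-2|z|/\mu}}{2},}
#' which is evaluated in the folded overflow-safe form on the right. It is
#' smooth, even, convex, and satisfies
#' \eqn{0 \le |z| - f_\mu(z) \le \mu \log 2} with the gap attaining its
#' supremum \eqn{\mu \log 2} as \eqn{|z| \to \infty}.
#'
#' `smooth_abs_grad()` is the exact derivative,
#' \eqn{(e^{z/\mu} - e^{-z/\mu})/(e^{z/\mu} + e^{-z/\mu}) = \tanh(z/\mu)},
#' an odd function with values in \eqn{(-1, 1)}.
#'
#' Both functions are vectorized over `z`.
#'
#' @param z numeric vector.
#' @param mu positive smoothing parameter.
#' @return `smooth_abs()`: the smoothed absolute values; `smooth_abs_grad()`:
#'   the derivatives, in `(-1, 1)`.
#' @examples
#' smooth_abs(5, mu = 0.1)        # 5 - 0.1 * log(2), to machine precision
#' smooth_abs_grad(0, mu = 0.1)   # 0
#' @export
smooth_abs <- function(z, mu) {
  check_mu(mu)
  if (!all(is.finite(z))) stop("'z' must be finite")
  az <- abs(z)
  az + mu * log1p(exp(-2 * az / mu)) - mu * log(2)
}

#' @rdname smooth_abs
#' @export
smooth_abs_grad <- function(z, mu) {
  check_mu(mu)
  tanh(z / mu)
}
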