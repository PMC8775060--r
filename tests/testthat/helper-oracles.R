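# Independent oracles the tests check the implementation against. None of
# these call the code paths they verify.

# brute-force piecewise maximum: explicit loop over rows of A
oracle_piecewise_max <- function(A, z) {
  best <- -Inf
  for (i in seq_len(nrow(A))) {
    v <- sum(A[i, ] * c(z, 1))
    if (v > best) best <- v
  }
  best
}

# central finite difference of a scalar function
fd_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

# exact (unsmoothed) Lassosum minimizer by coordinate descent with
# soft-thresholding; independent of the package's quasi-Newton path
oracle_cd_lassosum <- function(C, r, s, lambda, tol = 1e-12, max_sweeps = 5e4) {
  p <- length(r)
  b <- numeric(p)
  for (sweep in seq_len(max_sweeps)) {
    delta <- 0
    for (j in seq_len(p)) {
      cj <- (1 - s) * (sum(C[j, ] * b) - C[j, j] * b[j]) - r[j]
      aj <- (1 - s) * C[j, j] + s
      bj <- sign(-cj) * max(abs(cj) - lambda, 0) / aj
      delta <- max(delta, abs(bj - b[j]))
      b[j] <- bj
    }
    if (delta < tol) break
  }
  b
}

# P(Z1 > a, Z2 > b) for standard bivariate normal with correlation rho,
# by one-dimensional numeric integration
orthant_prob <- function(a, b, rho) {
  f <- function(z) dnorm(z) * pnorm((rho * z - b) / sqrt(1 - rho^2))
  integrate(f, a, Inf, rel.tol = 1e-10)$value
}

# expected correlation between two thresholded-Gaussian haplotype dosages
oracle_dosage_cor <- function(maf1, maf2, rho) {
  t1 <- qnorm(1 - maf1); t2 <- qnorm(1 - maf2)
  p11 <- orthant_prob(t1, t2, rho)
  (p11 - maf1 * maf2) / sqrt(maf1 * (1 - maf1) * maf2 * (1 - maf2))
}

# a random standardized-design Lassosum problem; returns the pieces the
# tests need alongside the constructed problem object
random_problem <- function(n = 30, p = 8, s = 0.5, lambda = 2^-3, seed = 1,
                           yty = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  X <- sweep(X, 2, colMeans(X))
  X <- sweep(X, 2, sqrt(colSums(X^2)), "/")
  u <- rnorm(n); u <- u / sqrt(sum(u^2))
  r <- drop(crossprod(X, u))
  list(X = X, u = u, r = r,
       prob = lassosum_problem(X, r, yty = yty, s = s, lambda = lambda))
}
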