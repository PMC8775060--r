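test_that("covariate residualization is exact ordinary least squares", {
  set.seed(30)
  y <- rnorm(40)
  # intercept-only regression centers the outcome
  cf <- regress_covariates(NULL, y)
  expect_equal(unname(cf$gamma_hat), mean(y))
  expect_equal(cf$residuals, y - mean(y))

  # a perfectly linear outcome leaves zero residuals
  Z <- matrix(rnorm(120), 40, 3)
  y_lin <- drop(2 + Z %*% c(1, -2, 0.5))
  expect_lt(max(abs(regress_covariates(Z, y_lin)$residuals)), 1e-10)

  # random instance against an independent normal-equations solve
  set.seed(31)
  Z <- matrix(rnorm(150), 50, 3)
  y <- rnorm(50)
  cf <- regress_covariates(Z, y)
  D <- cbind(1, Z)
  gamma_ne <- solve(crossprod(D), crossprod(D, y))
  expect_equal(unname(cf$gamma_hat), drop(gamma_ne), tolerance = 1e-10)
  expect_equal(cf$residuals, y - drop(D %*% gamma_ne), tolerance = 1e-10)
  # residuals are orthogonal to every covariate and sum to zero
  expect_lt(max(abs(crossprod(Z, cf$residuals))), 1e-10)
  expect_lt(abs(sum(cf$residuals)), 1e-10)
})

test_that("collinear covariates raise an error naming the offender", {
  set.seed(32)
  Z <- matrix(rnorm(60), 30, 2)
  Z <- cbind(Z, dup = Z[, 1] * 2)
  colnames(Z) <- c("age", "sex", "age_again")
  expect_error(regress_covariates(Z, rnorm(30)), "age_again")
})

test_that("residual correlations match per-column dot products", {
  set.seed(33)
  X <- matrix(rnorm(200), 20, 10)
  std <- standardize_dosages(X)
  expect_equal(residual_correlations(std$X_std, numeric(20)), numeric(10))

  u <- std$X_std[, 1]  # unit-norm column correlates perfectly with itself
  expect_equal(residual_correlations(std$X_std, u)[1], 1, tolerance = 1e-12)

  res <- rnorm(20)
  r <- suppressWarnings(residual_correlations(std$X_std, res))
  r_loop <- vapply(1:10, function(j) sum(std$X_std[, j] * res), numeric(1))
  expect_equal(r, r_loop, tolerance = 1e-12)

  big <- rnorm(20, sd = 10)
  expect_warning(residual_correlations(std$X_std, big), "outside")
})

test_that("covariate orthogonality carries through to the correlations", {
  set.seed(34)
  Z <- matrix(rnorm(300), 100, 3)
  y <- drop(Z %*% c(1, 2, 3)) + rnorm(100)
  cf <- regress_covariates(Z, y)
  stdZ <- standardize_dosages(Z)
  r <- residual_correlations(stdZ$X_std, cf$residuals)
  expect_lt(max(abs(r)), 1e-10)
})

test_that("a purely covariate-driven outcome yields a near-null SNP model", {
  cfg <- simulation_config(n = 500, p = 50, h2 = 0, n_causal = 0,
                           covariate_effects = c(0.6, 0.4), seed = 35)
  sim <- simulate_genotypes(cfg)
  ph <- simulate_phenotype(sim$panel, cfg)
  fit <- irm(sim$panel, ph$y, ph$Z)
  expect_lt(max(abs(fit$beta_hat)), 0.05)
})

test_that("fitting with no covariates is a PRS on the centered outcome", {
  cfg <- simulation_config(n = 200, p = 30, n_causal = 3,
                           covariate_effects = numeric(0), seed = 36)
  sim <- simulate_genotypes(cfg)
  ph <- simulate_phenotype(sim$panel, cfg)
  fit <- irm(sim$panel, ph$y)
  expect_equal(unname(fit$gamma_hat), mean(ph$y))
  # reproduce the pipeline by hand on the centered outcome
  std <- standardize_dosages(sim$panel$dosages)
  u <- ph$y - mean(ph$y)
  r <- residual_correlations(std$X_std, u / sqrt(sum(u^2)))
  ref <- fit_smoothed_lassosum(
    lassosum_problem(std$X_std, r, yty = 1), fit_config())
  expect_equal(unname(fit$beta_hat), ref$beta_hat, tolerance = 1e-8)
})

test_that("prediction composes covariate and SNP parts correctly", {
  cfg <- simulation_config(n = 300, p = 40, n_causal = 5, seed = 37)
  sim <- simulate_genotypes(cfg)
  ph <- simulate_phenotype(sim$panel, cfg)
  fit <- irm(sim$panel, ph$y, ph$Z)

  # beta = 0 reduces to the covariate-only prediction
  fit0 <- fit
  fit0$beta_hat[] <- 0
  expect_equal(unname(predict(fit0, sim$panel, ph$Z)),
               drop(cbind(1, ph$Z) %*% fit$gamma_hat))

  # permuting rows of the new data permutes the predictions identically
  yhat <- predict(fit, sim$panel$dosages, ph$Z)
  perm <- sample(nrow(sim$panel$dosages))
  expect_equal(unname(predict(fit, sim$panel$dosages[perm, ], ph$Z[perm, ])),
               unname(yhat[perm]))

  # variant mismatch is reported with the missing ids
  expect_error(predict(fit, sim$panel$dosages[, 1:10], ph$Z),
               "lack fitted variant")
})

test_that("a noise-free linear simulation is recovered on its training set", {
  cfg <- simulation_config(n = 300, p = 20, n_causal = 5, h2 = 1,
                           covariate_effects = numeric(0), seed = 38)
  sim <- simulate_genotypes(cfg)
  ph <- simulate_phenotype(sim$panel, cfg)
  fit <- irm(sim$panel, ph$y, cfg = fit_config(lambda = 1e-4, s = 0.01))
  yhat <- predict(fit, sim$panel)
  expect_gt(cor(yhat, ph$y), 0.999)
  expect_lt(mean(abs(yhat - ph$y)), 0.05 * sd(ph$y))
})

test_that("causal effect signs are recovered on the default simulation", {
  cfg <- simulation_config(seed = 39)
  sim <- simulate_genotypes(cfg)
  ph <- simulate_phenotype(sim$panel, cfg)
  fit <- irm(sim$panel, ph$y, ph$Z)
  null_scale <- 1 / sqrt(cfg$n)
  strong <- which(abs(ph$true_beta) > 2 * null_scale)
  expect_gt(length(strong), 0)
  expect_identical(unname(sign(fit$beta_hat[strong])),
                   sign(ph$true_beta[strong]))
})

test_that("evaluation metrics match their defining counts", {
  rep0 <- evaluate_predictions(c(1, 2, 3), c(1, 2, 3), "continuous")
  expect_equal(rep0$mean_abs_residuals, 0)
  expect_equal(rep0$correlation, 1)
  expect_true(is.na(rep0$auc))

  # 3 of 4 case-control pairs concordant
  rep1 <- evaluate_predictions(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1), "binary")
  expect_equal(rep1$auc, 0.75)
  expect_equal(rep1$n_validation, 4)

  # reversing the scores flips the AUC
  rep2 <- evaluate_predictions(c(1, 1, 0, 0), -c(0.9, 0.4, 0.6, 0.1), "binary")
  expect_equal(rep2$auc, 1 - rep1$auc)

  # ties count one half
  rep3 <- suppressWarnings(evaluate_predictions(c(1, 0), c(0.5, 0.5), "binary"))
  expect_equal(rep3$auc, 0.5)

  expect_warning(ev <- evaluate_predictions(c(1, 0, 1), rep(0.2, 3), "binary"),
                 "constant")
  expect_true(is.na(ev$correlation))
  expect_error(evaluate_predictions(c(1, 2), c(1, 1, 1), "binary"), "mismatch")
  expect_error(evaluate_predictions(c(0.5, 1), c(0.1, 0.2), "binary"), "0/1")
})

test_that("validation error decreases with the training proportion", {
  cfg <- simulation_config(n = 400, p = 60, n_causal = 6, seed = 40)
  sim <- simulate_genotypes(cfg)
  ph <- simulate_phenotype(sim$panel, cfg)
  props <- c(0.2, 0.5, 0.8)
  mars <- sapply(props, function(pr) {
    mean(vapply(1:4, function(sd_i) {
      sp <- train_validation_split(cfg$n, pr, seed = 100 + sd_i)
      fit <- irm(sim$panel$dosages[sp$train, ], ph$y[sp$train],
                 ph$Z[sp$train, ])
      yhat <- predict(fit, sim$panel$dosages[sp$validation, ],
                      ph$Z[sp$validation, ])
      mean(abs(ph$y[sp$validation] - yhat))
    }, numeric(1)))
  })
  expect_true(all(diff(mars) < 0))
})

test_that("splits are reproducible and partition the samples", {
  s1 <- train_validation_split(100, 0.7, seed = 5)
  s2 <- train_validation_split(100, 0.7, seed = 5)
  expect_identical(s1, s2)
  expect_length(s1$train, 70)
  expect_setequal(c(s1$train, s1$validation), 1:100)
})
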