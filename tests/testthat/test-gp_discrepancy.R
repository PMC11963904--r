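test_that("squared-exponential kernel matches its printed form", {
  set.seed(1)
  g <- runif(5, 0.5, 2)
  x <- matrix(rnorm(5), 1)
  expect_equal(drop(se_kernel(x, x, 1.7, g)), 1.7, tolerance = 1e-15)

  # offset of exactly one correlation length in one coordinate
  x2 <- x
  x2[1, 3] <- x2[1, 3] + g[3]
  expect_equal(drop(se_kernel(x, x2, 1.7, g)), 1.7 * exp(-1),
               tolerance = 1e-12)

  A <- matrix(rnorm(20), 4, 5)
  B <- matrix(rnorm(15), 3, 5)
  expect_equal(se_kernel(A, B, 0.9, g), t(se_kernel(B, A, 0.9, g)),
               tolerance = 1e-15)
  expect_error(se_kernel(A, B, 1, c(-1, g[-1])), "positive")
})

test_that("derivative cross-covariances match finite differences of the kernel", {
  set.seed(2)
  g <- runif(5, 0.5, 2)
  x1 <- matrix(rnorm(5), 1)
  x2 <- matrix(rnorm(5), 1)
  h <- 1e-5
  for (j in c(1, 5)) {
    e <- rep(0, 5); e[j] <- h
    fd <- (se_kernel(x1, x2 + matrix(e, 1), 1.3, g) -
             se_kernel(x1, x2 - matrix(e, 1), 1.3, g)) / (2 * h)
    an <- se_kernel_value_deriv(x1, x2, 1.3, g, j)
    expect_equal(drop(an), drop(fd), tolerance = 1e-6)
  }
  # coincident inputs: value-derivative covariance vanishes,
  # derivative-derivative equals 2 sigma2 / gamma_j^2
  expect_equal(drop(se_kernel_value_deriv(x1, x1, 1.3, g, 5)), 0,
               tolerance = 1e-15)
  expect_equal(drop(se_kernel_deriv_deriv(x1, x1, 1.3, g, 5, 5)),
               2 * 1.3 / g[5]^2, tolerance = 1e-12)
  # second derivative via nested central differences
  e5 <- rep(0, 5); e5[5] <- h
  dd_fd <- (se_kernel_value_deriv(x1 + matrix(e5, 1), x2, 1.3, g, 5) -
              se_kernel_value_deriv(x1 - matrix(e5, 1), x2, 1.3, g, 5)) /
    (2 * h)
  expect_equal(drop(se_kernel_deriv_deriv(x1, x2, 1.3, g, 5, 5)),
               drop(dd_fd), tolerance = 1e-5)
})

test_that("inverse-gamma priors reproduce the stated mean/mode pairs", {
  ig <- inverse_gamma_from_mean_mode(0.3^2, 0.2^2)
  expect_equal(ig$shape, 2.6, tolerance = 1e-12)
  expect_equal(ig$scale, 0.144, tolerance = 1e-12)
  expect_equal(ig$scale / (ig$shape - 1), 0.09, tolerance = 1e-12)
  expect_equal(ig$scale / (ig$shape + 1), 0.04, tolerance = 1e-12)
  ig2 <- inverse_gamma_from_mean_mode(0.016^2, 0.015^2)
  expect_equal(ig2$scale / (ig2$shape - 1), 0.016^2, tolerance = 1e-15)
  expect_equal(ig2$scale / (ig2$shape + 1), 0.015^2, tolerance = 1e-15)
  expect_error(inverse_gamma_from_mean_mode(0.01, 0.02), "mean > mode")
})

test_that("log posterior is marginal likelihood plus log priors", {
  set.seed(3)
  Xs <- matrix(rnorm(25), 5, 5)
  r <- rnorm(5, 0, 0.1)
  Vs <- matrix(rnorm(10), 2, 5)
  Ds <- matrix(rnorm(10), 2, 5)
  priors <- gp_priors()
  hyper <- list(sigma2 = 0.05, gamma = runif(5, 1, 4), sigmae2 = 1e-4)
  lp <- gp_log_posterior(hyper, Xs, r, Vs, Ds, 5L, priors)

  # independent dense recomputation of both parts
  K <- odcdisc:::gp_joint_cov(Xs, Vs, Ds, 5L, hyper$sigma2, hyper$gamma,
                              hyper$sigmae2)
  y <- c(r, rep(0, 4))
  ll <- dense_mvn_logpdf(y, K)
  pri <- odcdisc:::log_dinvgamma(hyper$sigma2, priors$sigma2$shape,
                                 priors$sigma2$scale) +
    sum(stats::dgamma(hyper$gamma[1:4], 42, rate = 9, log = TRUE)) +
    stats::dgamma(hyper$gamma[5], 4, rate = 4, log = TRUE) +
    odcdisc:::log_dinvgamma(hyper$sigmae2, priors$sigmae2$shape,
                            priors$sigmae2$scale)
  expect_equal(lp, ll + pri, tolerance = 1e-8)

  # prior tails: an absurd correlation length lowers the posterior
  far <- hyper; far$gamma[5] <- 1e6
  expect_lt(gp_log_posterior(far, Xs, r, Vs, Ds, 5L, priors), lp)
})

test_that("MAP fitting is deterministic, ascends, and recovers known hyperparameters", {
  # data simulated from the prior model itself
  set.seed(10)
  X <- make_input_grid(80, seed = 10)
  std <- odcdisc:::standardize_fit(X)
  Xs <- odcdisc:::standardize_apply(X, std)
  true_sigma2 <- 0.04
  K <- se_kernel(Xs, Xs, true_sigma2, c(4, 4, 4, 4, 0.8))
  L <- chol(K + diag(1e-10, 80))
  delta <- drop(t(L) %*% rnorm(80))
  z <- sa_baseline(X) + delta + rnorm(80, 0, 0.005)

  fit1 <- fit_gp_discrepancy(X, z, n_starts = 3, seed = 99)
  fit2 <- fit_gp_discrepancy(X, z, n_starts = 3, seed = 99)
  expect_identical(fit1$hyper, fit2$hyper)
  expect_true(all(fit1$log_posterior >= fit1$start_values - 1e-6))
  expect_lt(abs(log(fit1$hyper$sigma2) - log(true_sigma2)), 1)
})

test_that("predictions equal dense joint-Gaussian conditioning on small instances", {
  set.seed(4)
  X <- make_input_grid(10, seed = 4)
  z <- sa_baseline(X) + 0.1 * sin(X[, "p"]) + rnorm(10, 0, 0.01)
  fit <- fit_gp_discrepancy(X, z, n_starts = 2, seed = 5)
  # 10 data + 2 value + 2 derivative constraint points = 14 <= 20
  X_new <- make_input_grid(6, seed = 6)
  pred <- gp_predict(fit, X_new)
  oracle <- oracle_gp_predict(fit, X_new)
  expect_equal(pred$delta_mean, oracle$delta_mean, tolerance = 1e-8)
  expect_equal(pred$delta_sd^2, oracle$delta_var, tolerance = 1e-8)
  expect_equal(pred$mean, sa_baseline(X_new) + oracle$delta_mean,
               tolerance = 1e-8)
})

test_that("posterior honours the value and derivative constraints", {
  run <- gp_run(0.05)
  cpts <- run$gp$constraints$value_points
  pc <- gp_predict(run$gp, cpts)
  expect_lt(max(abs(pc$delta_mean)), 1e-6)
  expect_lt(max(pc$delta_sd), 1e-4)
})

test_that("updated model beats the baseline and is calibrated on held-out data", {
  run <- gp_run(0.05)
  expect_lt(run$rmse_gp, run$rmse_baseline)
  va <- dataset_partition(run$dataset, "validation")
  coverage <- mean(abs(run$pred$mean - va$s_true) <= 2 * run$pred$sd)
  # binomial tolerance at n = 50 around the nominal 95%
  expect_gte(coverage, 0.85)
})

test_that("posterior reverts to the prior far from data and constraints", {
  set.seed(8)
  X <- make_input_grid(10, seed = 8)
  z <- sa_baseline(X) + 0.05
  fit <- fit_gp_discrepancy(X, z, n_starts = 2, seed = 8)
  # far outside the standardized training cloud
  X_far <- matrix(c(7.3, 6, 0.01, 37, 9.8), 1,
                  dimnames = list(NULL, colnames(X)))
  X_far[, "pH"] <- 9.5
  X_far[, "PCO2"] <- 40
  pred <- gp_predict(fit, X_far)
  expect_equal(pred$delta_sd^2, fit$hyper$sigma2, tolerance = 0.05)
  expect_equal(pred$mean, pred$f + pred$delta_mean, tolerance = 1e-12)
})

test_that("interpolation limit: with tiny noise the posterior passes through residuals", {
  set.seed(9)
  X <- make_input_grid(12, seed = 9)
  z <- sa_baseline(X) + 0.08 * cos(log(X[, "p"]))
  fit <- fit_gp_discrepancy(X, z, n_starts = 2, seed = 9,
                            fixed_sigmae2 = 1e-10)
  pred <- gp_predict(fit, X)
  expect_equal(pred$mean, z, tolerance = 1e-3)
})
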