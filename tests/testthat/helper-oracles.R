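# Independent dense-linear-algebra oracles, deliberately written with
# solve()/determinant() rather than the package's Cholesky path.

dense_mvn_logpdf <- function(y, K) {
  n <- length(y)
  ld <- as.numeric(determinant(K, logarithm = TRUE)$modulus)
  -0.5 * drop(t(y) %*% solve(K, y)) - 0.5 * ld - n / 2 * log(2 * pi)
}

# Textbook joint-Gaussian conditioning: mean and variance of delta at new
# points given the stacked observation vector y with joint covariance K
# (data noise already on its diagonal) and cross-covariance Ks (new x
# joint).
dense_gp_conditional <- function(Ks, K, y, prior_var) {
  Kinv_y <- solve(K, y)
  mean <- drop(Ks %*% Kinv_y)
  var <- prior_var - diag(Ks %*% solve(K, t(Ks)))
  list(mean = mean, var = pmax(var, 0))
}

# Joint covariance and cross blocks of a fitted gp_discrepancy model,
# rebuilt from exported kernel functions only (no internal factorization).
oracle_gp_predict <- function(model, X_new) {
  h <- model$hyper
  Xs <- model$Xs; Vs <- model$Vs; Ds <- model$Ds; dc <- model$dcoord
  Kxx <- se_kernel(Xs, Xs, h$sigma2, h$gamma)
  diag(Kxx) <- diag(Kxx) + h$sigmae2
  K <- rbind(
    cbind(Kxx,
          se_kernel(Xs, Vs, h$sigma2, h$gamma),
          se_kernel_value_deriv(Xs, Ds, h$sigma2, h$gamma, dc)),
    cbind(se_kernel(Vs, Xs, h$sigma2, h$gamma),
          se_kernel(Vs, Vs, h$sigma2, h$gamma),
          se_kernel_value_deriv(Vs, Ds, h$sigma2, h$gamma, dc)),
    cbind(t(se_kernel_value_deriv(Xs, Ds, h$sigma2, h$gamma, dc)),
          t(se_kernel_value_deriv(Vs, Ds, h$sigma2, h$gamma, dc)),
          se_kernel_deriv_deriv(Ds, Ds, h$sigma2, h$gamma, dc, dc)))
  K <- K + diag(model$jitter, nrow(K))
  Xn <- sweep(sweep(as.matrix(X_new), 2, model$std$center, "-"),
              2, model$std$scale, "/")
  Ks <- cbind(se_kernel(Xn, Xs, h$sigma2, h$gamma),
              se_kernel(Xn, Vs, h$sigma2, h$gamma),
              se_kernel_value_deriv(Xn, Ds, h$sigma2, h$gamma, dc))
  cond <- dense_gp_conditional(Ks, K, model$y, h$sigma2)
  list(delta_mean = cond$mean, delta_var = cond$var)
}

make_input_grid <- function(n, seed = 1) {
  set.seed(seed)
  cbind(pH = stats::runif(n, 7.0, 7.6),
        PCO2 = stats::runif(n, 3, 9),
        FMetHb = stats::runif(n, 0, 0.02),
        T_cel = stats::runif(n, 35, 39),
        p = exp(stats::runif(n, log(2), log(10))))
}
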