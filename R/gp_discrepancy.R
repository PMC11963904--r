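#' Squared-exponential covariance between input sets
#'
#' The separable squared-exponential kernel
#' `k(x, x') = sigma2 * exp(-sum_i ((x_i - x'_i) / gamma_i)^2)` — note the
#' squared ratio per coordinate and no factor 1/2. Inputs are expected on
#' the standardized scale used for fitting.
#'
#' @param X1,X2 matrices with one input per row, equal column count.
#' @param sigma2 kernel variance (squared-saturation units).
#' @param gamma vector of correlation lengths, one per input coordinate;
#'   strictly positive.
#' @return `nrow(X1) x nrow(X2)` covariance matrix.
#' @export
se_kernel <- function(X1, X2, sigma2, gamma) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  if (ncol(X1) != ncol(X2)) stop("input dimensions differ", call. = FALSE)
  if (length(gamma) != ncol(X1))
    stop("gamma length must match input dimension", call. = FALSE)
  if (any(gamma <= 0)) stop("gamma must be strictly positive", call. = FALSE)
  D2 <- matrix(0, nrow(X1), nrow(X2))
  for (i in seq_len(ncol(X1))) {
    D2 <- D2 + outer(X1[, i], X2[, i], "-")^2 / gamma[i]^2
  }
  sigma2 * exp(-D2)
}

#' Covariance between process values and partial derivatives
#'
#' Cross-covariance blocks obtained by differentiating the
#' squared-exponential kernel, used to condition the discrepancy process on
#' noise-free derivative observations.
#' `cov(delta(x), d delta(x')/dx'_j) = k(x, x') * 2 (x_j - x'_j) / gamma_j^2`.
#'
#' @inheritParams se_kernel
#' @param j index of the differentiated coordinate (in `X2`).
#' @return `nrow(X1) x nrow(X2)` covariance matrix.
#' @export
se_kernel_value_deriv <- function(X1, X2, sigma2, gamma, j) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  if (j < 1 || j > ncol(X1)) stop("invalid derivative coordinate", call. = FALSE)
  K <- se_kernel(X1, X2, sigma2, gamma)
  K * (2 * outer(X1[, j], X2[, j], "-") / gamma[j]^2)
}

#' Covariance between partial derivatives of the process
#'
#' `cov(d delta(x)/dx_i, d delta(x')/dx'_j)` for the squared-exponential
#' kernel: `k(x,x') * (2 * 1[i==j] / gamma_i^2 -
#' 4 (x_i - x'_i)(x_j - x'_j) / (gamma_i^2 gamma_j^2))`. At coincident
#' inputs with `i == j` this is `2 * sigma2 / gamma_j^2`.
#'
#' @inheritParams se_kernel
#' @param i,j differentiated coordinates in `X1` and `X2` respectively.
#' @return `nrow(X1) x nrow(X2)` covariance matrix.
#' @export
se_kernel_deriv_deriv <- function(X1, X2, sigma2, gamma, i, j) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  if (i < 1 || i > ncol(X1) || j < 1 || j > ncol(X1))
    stop("invalid derivative coordinate", call. = FALSE)
  K <- se_kernel(X1, X2, sigma2, gamma)
  Ui <- outer(X1[, i], X2[, i], "-")
  Uj <- outer(X1[, j], X2[, j], "-")
  K * (2 * (i == j) / gamma[i]^2 - 4 * Ui * Uj / (gamma[i]^2 * gamma[j]^2))
}

#' Solve inverse-gamma shape and scale from mean and mode
#'
#' For an Inverse-Gamma(shape, scale) density, `mean = scale/(shape - 1)`
#' and `mode = scale/(shape + 1)`; given both, `shape = (mean + mode) /
#' (mean - mode)` and `scale = mean * (shape - 1)`. Requires `mean > mode`.
#'
#' @param mean,mode target mean and mode; both positive, `mean > mode`.
#' @return List with `shape` and `scale`.
#' @export
inverse_gamma_from_mean_mode <- function(mean, mode) {
  if (mean <= mode) stop("inverse-gamma requires mean > mode", call. = FALSE)
  shape <- (mean + mode) / (mean - mode)
  list(shape = shape, scale = mean * (shape - 1))
}

log_dinvgamma <- function(x, shape, scale) {
  shape * log(scale) - lgamma(shape) - (shape + 1) * log(x) - scale / x
}

#' Hyperparameter priors for the discrepancy GP
#'
#' Default priors of the synthetic study, on the standardized-input scale:
#' Inverse-Gamma on the kernel variance `sigma2` with mean 0.3^2 and mode
#' 0.2^2; Gamma(4, 4) (shape-rate) on the correlation length of the
#' pressure coordinate; Gamma(42, 9) on the four remaining correlation
#' lengths (a deliberately smoother prior); Inverse-Gamma on the
#' observation-error variance `sigma_e2` with mean 0.016^2 and mode
#' 0.015^2.
#'
#' @param sigma2_mean,sigma2_mode mean and mode of the Inverse-Gamma prior
#'   on the kernel variance.
#' @param gamma_p shape and rate of the Gamma prior on the p-direction
#'   correlation length.
#' @param gamma_other shape and rate of the Gamma prior on the remaining
#'   correlation lengths.
#' @param sigmae2_mean,sigmae2_mode mean and mode of the Inverse-Gamma
#'   prior on the observation-error variance.
#' @return A list of class `gp_priors`.
#' @export
gp_priors <- function(sigma2_mean = 0.3^2, sigma2_mode = 0.2^2,
                      gamma_p = c(4, 4), gamma_other = c(42, 9),
                      sigmae2_mean = 0.016^2, sigmae2_mode = 0.015^2) {
  structure(list(
    sigma2 = inverse_gamma_from_mean_mode(sigma2_mean, sigma2_mode),
    gamma_p = list(shape = gamma_p[1], rate = gamma_p[2]),
    gamma_other = list(shape = gamma_other[1], rate = gamma_other[2]),
    sigmae2 = inverse_gamma_from_mean_mode(sigmae2_mean, sigmae2_mode)
  ), class = "gp_priors")
}

#' Constraint set for the discrepancy process
#'
#' Value constraints `delta(x) = 0` and derivative constraints
#' `d delta / d p = 0` at low and high combined pressures with the other
#' inputs at reference values. These encode the clinical prior that the
#' mechanistic model is trusted at the extremes of the pressure range,
#' where saturation saturates at 0 or 1 and the discrepancy must vanish.
#'
#' @param p_extremes pressures (kPa) at which both constraint types are
#'   placed; default `c(0.5, 45)`, just outside the sampling range.
#' @param reference named vector of the non-pressure inputs at which the
#'   constraints sit.
#' @return A list of class `gp_constraints` with matrices `value_points`
#'   and `deriv_points` (5 columns: pH, PCO2, FMetHb, T_cel, p) and
#'   `deriv_coord = 5`.
#' @export
gp_constraints <- function(p_extremes = c(0.5, 45),
                           reference = c(pH = 7.40, PCO2 = 5.33,
                                         FMetHb = 0, T_cel = 37)) {
  pts <- cbind(pH = rep(reference[["pH"]], length(p_extremes)),
               PCO2 = reference[["PCO2"]], FMetHb = reference[["FMetHb"]],
               T_cel = reference[["T_cel"]], p = p_extremes)
  structure(list(value_points = pts, deriv_points = pts, deriv_coord = 5L),
            class = "gp_constraints")
}

#' Baseline mechanistic prediction from an input matrix
#'
#' Evaluates the Siggaard-Andersen model with `a4 = 0` over rows of the
#' standard 5-column input matrix (pH, PCO2, FMetHb, T_cel, p). This is the
#' `f(x)` that the additive discrepancy corrects.
#'
#' @param X matrix or data frame with columns `pH, PCO2, FMetHb, T_cel, p`.
#' @return Vector of combined saturations.
#' @export
sa_baseline <- function(X) {
  X <- as.matrix(X)
  sa_predict(X[, "pH"], X[, "PCO2"], X[, "FMetHb"],
             T_cel = X[, "T_cel"], p = X[, "p"], a4_override = 0)
}

standardize_fit <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  list(center = ctr, scale = scl)
}

standardize_apply <- function(X, std) {
  sweep(sweep(as.matrix(X), 2, std$center, "-"), 2, std$scale, "/")
}

# Joint covariance over [data, value constraints, p-derivative constraints]
# on the standardized scale. Constraints are noise-free; only the data block
# receives the observation-error variance.
gp_joint_cov <- function(Xs, Vs, Ds, dcoord, sigma2, gamma, sigmae2) {
  Kxx <- se_kernel(Xs, Xs, sigma2, gamma)
  diag(Kxx) <- diag(Kxx) + sigmae2
  Kxv <- se_kernel(Xs, Vs, sigma2, gamma)
  Kxd <- se_kernel_value_deriv(Xs, Ds, sigma2, gamma, dcoord)
  Kvv <- se_kernel(Vs, Vs, sigma2, gamma)
  Kvd <- se_kernel_value_deriv(Vs, Ds, sigma2, gamma, dcoord)
  Kdd <- se_kernel_deriv_deriv(Ds, Ds, sigma2, gamma, dcoord, dcoord)
  rbind(cbind(Kxx, Kxv, Kxd),
        cbind(t(Kxv), Kvv, Kvd),
        cbind(t(Kxd), t(Kvd), Kdd))
}

# Cholesky with a jitter ladder; returns list(L, jitter) or an error.
chol_jitter <- function(K, ladder = 10^seq(-10, -6)) {
  for (j in c(0, ladder)) {
    L <- tryCatch(chol(K + diag(j, nrow(K))), error = function(e) NULL)
    if (!is.null(L)) return(list(L = L, jitter = j))
  }
  stop("joint covariance not positive definite after maximum jitter ",
       "(1e-6); check hyperparameters", call. = FALSE)
}

# Gaussian log marginal likelihood of y under covariance K (via Cholesky).
gp_log_marginal <- function(y, K) {
  cj <- chol_jitter(K)
  a <- backsolve(cj$L, backsolve(cj$L, y, transpose = TRUE))
  -0.5 * sum(y * a) - sum(log(diag(cj$L))) - length(y) / 2 * log(2 * pi)
}

#' Unnormalized log posterior of the GP hyperparameters
#'
#' Gaussian marginal likelihood of the residuals jointly with the
#' noise-free constraint observations (zeros), plus the log prior
#' densities of [gp_priors()].
#'
#' @param hyper list with `sigma2`, `gamma` (length 5) and `sigmae2`.
#' @param Xs standardized training inputs.
#' @param r residuals `z - f(x)` at the training inputs.
#' @param Vs,Ds standardized value- and derivative-constraint locations.
#' @param dcoord derivative coordinate index.
#' @param priors a [gp_priors()] object.
#' @return Scalar log density (unnormalized).
#' @export
gp_log_posterior <- function(hyper, Xs, r, Vs, Ds, dcoord, priors) {
  K <- gp_joint_cov(Xs, Vs, Ds, dcoord,
                    hyper$sigma2, hyper$gamma, hyper$sigmae2)
  y <- c(r, rep(0, nrow(Vs) + nrow(Ds)))
  ll <- gp_log_marginal(y, K)
  lp <- log_dinvgamma(hyper$sigma2, priors$sigma2$shape, priors$sigma2$scale) +
    sum(stats::dgamma(hyper$gamma[-dcoord], shape = priors$gamma_other$shape,
                      rate = priors$gamma_other$rate, log = TRUE)) +
    stats::dgamma(hyper$gamma[dcoord], shape = priors$gamma_p$shape,
                  rate = priors$gamma_p$rate, log = TRUE) +
    log_dinvgamma(hyper$sigmae2, priors$sigmae2$shape, priors$sigmae2$scale)
  ll + lp
}

#' Fit the constrained GP discrepancy model by MAP
#'
#' Models observations as `z = f(x) + delta(x) + e` with `f` the a4 = 0
#' mechanistic model, `delta` a zero-mean GP with separable
#' squared-exponential kernel, and `e` Gaussian noise. The process and its
#' pressure-derivative are conditioned to zero at the constraint locations.
#' Hyperparameters (kernel variance, five correlation lengths, noise
#' variance) are estimated by maximum a posteriori with multi-start
#' L-BFGS on the log scale, starts drawn from the priors.
#'
#' @param X training inputs: matrix with columns `pH, PCO2, FMetHb, T_cel,
#'   p`.
#' @param z observed combined saturations at `X`.
#' @param baseline function mapping the input matrix to the mechanistic
#'   prediction (default [sa_baseline()]).
#' @param priors a [gp_priors()] object.
#' @param constraints a [gp_constraints()] object.
#' @param n_starts number of optimization starts (default 8).
#' @param seed seed for the start draws.
#' @param fixed_sigmae2 if non-`NULL`, the observation-error variance is
#'   fixed at this value and excluded from optimization (clinical mode,
#'   where recorded saturations are treated as highly accurate).
#' @return A list of class `gp_discrepancy` with the MAP hyperparameters,
#'   standardization parameters, cached Cholesky factorization and the
#'   optimization trace.
#' @export
fit_gp_discrepancy <- function(X, z, baseline = sa_baseline,
                               priors = gp_priors(),
                               constraints = gp_constraints(),
                               n_starts = 8, seed = 1L,
                               fixed_sigmae2 = NULL) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 data points", call. = FALSE)
  f <- baseline(X)
  r <- z - f
  std <- standardize_fit(X)
  Xs <- standardize_apply(X, std)
  Vs <- standardize_apply(constraints$value_points, std)
  Ds <- standardize_apply(constraints$deriv_points, std)
  dcoord <- constraints$deriv_coord

  fixed_noise <- !is.null(fixed_sigmae2)
  obj <- function(theta) {
    hyper <- list(sigma2 = exp(theta[1]), gamma = exp(theta[2:6]),
                  sigmae2 = if (fixed_noise) fixed_sigmae2 else exp(theta[7]))
    lp <- tryCatch(
      gp_log_posterior(hyper, Xs, r, Vs, Ds, dcoord, priors),
      error = function(e) -Inf)
    if (!is.finite(lp)) return(1e10)
    -lp
  }

  set.seed(seed)
  n_par <- if (fixed_noise) 6L else 7L
  starts <- replicate(n_starts, {
    s2 <- priors$sigma2$scale / stats::rgamma(1, priors$sigma2$shape)
    g <- stats::rgamma(5, priors$gamma_other$shape,
                       rate = priors$gamma_other$rate)
    g[dcoord] <- stats::rgamma(1, priors$gamma_p$shape,
                               rate = priors$gamma_p$rate)
    se2 <- priors$sigmae2$scale / stats::rgamma(1, priors$sigmae2$shape)
    log(c(s2, g, se2))[seq_len(n_par)]
  })
  fits <- apply(starts, 2, function(th0) {
    stats::optim(th0, obj, method = "L-BFGS-B",
                 lower = rep(log(1e-8), n_par),
                 upper = rep(log(1e4), n_par),
                 control = list(maxit = 200))
  })
  vals <- vapply(fits, function(f) f$value, numeric(1))
  best <- fits[[which.min(vals)]]
  theta <- best$par
  hyper <- list(sigma2 = exp(theta[1]), gamma = exp(theta[2:6]),
                sigmae2 = if (fixed_noise) fixed_sigmae2 else exp(theta[7]))

  K <- gp_joint_cov(Xs, Vs, Ds, dcoord,
                    hyper$sigma2, hyper$gamma, hyper$sigmae2)
  cj <- chol_jitter(K)
  y <- c(r, rep(0, nrow(Vs) + nrow(Ds)))
  alpha <- backsolve(cj$L, backsolve(cj$L, y, transpose = TRUE))

  structure(list(
    hyper = hyper, priors = priors, constraints = constraints,
    std = std, X = X, Xs = Xs, Vs = Vs, Ds = Ds, dcoord = dcoord,
    r = r, y = y, L = cj$L, jitter = cj$jitter, alpha = alpha,
    baseline = baseline,
    log_posterior = -best$value,
    start_values = -vals
  ), class = "gp_discrepancy")
}

#' @export
print.gp_discrepancy <- function(x, ...) {
  cat("<gp_discrepancy> MAP fit on", nrow(x$X), "points,",
      nrow(x$Vs), "value +", nrow(x$Ds), "derivative constraints\n")
  cat(sprintf("  sigma2 = %.4g, sigma_e2 = %.4g\n",
              x$hyper$sigma2, x$hyper$sigmae2))
  cat("  gamma =", paste(sprintf("%.3g", x$hyper$gamma), collapse = ", "),
      "(standardized scale)\n")
  invisible(x)
}

#' Predict from a fitted GP discrepancy model
#'
#' Conditional mean and standard deviation of the updated model
#' `f(x) + delta(x)` at new inputs, given the residual data and the
#' noise-free constraint block. The default SD is for the latent updated
#' model; set `include_noise = TRUE` for observation-level intervals.
#'
#' @param model a fitted [fit_gp_discrepancy()] object.
#' @param X_new matrix of new inputs (same 5 columns as training).
#' @param include_noise add the observation-error variance to the
#'   predictive variance.
#' @return Data frame with columns `mean` (= f + posterior mean of delta),
#'   `sd`, `delta_mean`, `delta_sd` and `f`.
#' @export
gp_predict <- function(model, X_new, include_noise = FALSE) {
  if (!inherits(model, "gp_discrepancy"))
    stop("model must be a fitted gp_discrepancy", call. = FALSE)
  X_new <- as.matrix(X_new)
  Xn <- standardize_apply(X_new, model$std)
  h <- model$hyper
  Kx <- cbind(
    se_kernel(Xn, model$Xs, h$sigma2, h$gamma),
    se_kernel(Xn, model$Vs, h$sigma2, h$gamma),
    se_kernel_value_deriv(Xn, model$Ds, h$sigma2, h$gamma, model$dcoord))
  delta_mean <- drop(Kx %*% model$alpha)
  V <- backsolve(model$L, t(Kx), transpose = TRUE)
  var_d <- pmax(h$sigma2 - colSums(V^2), 0)
  if (include_noise) var_d <- var_d + h$sigmae2
  f <- model$baseline(X_new)
  data.frame(mean = f + delta_mean, sd = sqrt(var_d),
             delta_mean = delta_mean, delta_sd = sqrt(pmax(
               h$sigma2 - colSums(V^2), 0)), f = f)
}
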