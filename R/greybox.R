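#' Architecture of the embedded a4 network
#'
#' A fully connected network mapping the five physiological inputs
#' (pH, PCO2, FMetHb, T, p) to a single unitless a4 displacement. The
#' synthetic study uses two hidden layers of 20 neurons with the simplified
#' radial-basis activation `rbf(x) = exp(-x^2)`; clinical-scale fits use
#' wider layers (64) with the exponential linear unit.
#'
#' @param n_inputs input dimension (default 5).
#' @param hidden integer vector of hidden-layer widths.
#' @param activation `"rbf"` or `"elu"` (standard ELU, alpha = 1).
#' @return A list of class `network_spec`.
#' @export
network_spec <- function(n_inputs = 5, hidden = c(20, 20),
                         activation = c("rbf", "elu")) {
  activation <- match.arg(activation)
  if (any(hidden <= 0)) stop("hidden widths must be positive", call. = FALSE)
  structure(list(n_inputs = n_inputs, hidden = as.integer(hidden),
                 activation = activation),
            class = "network_spec")
}

act_fun <- function(z, activation) {
  switch(activation,
         rbf = exp(-z^2),
         elu = ifelse(z > 0, z, exp(pmin(z, 0)) - 1))
}

act_grad <- function(z, activation) {
  switch(activation,
         rbf = -2 * z * exp(-z^2),
         elu = ifelse(z > 0, 1, exp(pmin(z, 0))))
}

nn_shapes <- function(spec) {
  dims <- c(spec$n_inputs, spec$hidden, 1L)
  lapply(seq_len(length(dims) - 1), function(l) {
    c(out = dims[l + 1], `in` = dims[l])
  })
}

nn_n_params <- function(spec) {
  sum(vapply(nn_shapes(spec), function(s) s[1] * s[2] + s[1], numeric(1)))
}

nn_unflatten <- function(par, spec) {
  shapes <- nn_shapes(spec)
  out <- vector("list", length(shapes))
  pos <- 0L
  for (l in seq_along(shapes)) {
    s <- shapes[[l]]
    nw <- s[1] * s[2]
    W <- matrix(par[pos + seq_len(nw)], s[1], s[2])
    b <- par[pos + nw + seq_len(s[1])]
    pos <- pos + nw + s[1]
    out[[l]] <- list(W = W, b = b)
  }
  out
}

nn_flatten <- function(layers) {
  unlist(lapply(layers, function(l) c(as.vector(l$W), l$b)), use.names = FALSE)
}

#' Initialize network weights
#'
#' Glorot-uniform weights (`limit = sqrt(6 / (fan_in + fan_out))`) and zero
#' biases, deterministic given the seed.
#'
#' @param spec a [network_spec()].
#' @param seed integer seed.
#' @return A list of class `greybox_network` with the spec, the flattened
#'   parameter vector and (initially `NULL`) input standardization.
#' @export
init_network <- function(spec, seed = 1L) {
  set.seed(seed)
  layers <- lapply(nn_shapes(spec), function(s) {
    lim <- sqrt(6 / (s[1] + s[2]))
    list(W = matrix(stats::runif(s[1] * s[2], -lim, lim), s[1], s[2]),
         b = rep(0, s[1]))
  })
  structure(list(spec = spec, par = nn_flatten(layers), std = NULL,
                 loss_trajectory = NULL),
            class = "greybox_network")
}

# Forward pass on (already standardized) inputs; returns output row vector
# and per-layer caches for backprop. Xs is n x p; internally columns are
# samples.
nn_forward <- function(par, spec, Xs) {
  layers <- nn_unflatten(par, spec)
  A <- t(Xs)                      # p x n
  caches <- vector("list", length(layers))
  for (l in seq_along(layers)) {
    Z <- layers[[l]]$W %*% A + layers[[l]]$b
    caches[[l]] <- list(A_prev = A, Z = Z)
    A <- if (l < length(layers)) act_fun(Z, spec$activation) else Z
  }
  list(out = drop(A), caches = caches, layers = layers)
}

# Backward pass: dL/d(flattened params) given dL/d(output) (length n).
nn_backward <- function(fwd, spec, dout) {
  layers <- fwd$layers
  grads <- vector("list", length(layers))
  dA <- matrix(dout, nrow = 1)    # 1 x n
  for (l in rev(seq_along(layers))) {
    cache <- fwd$caches[[l]]
    dZ <- if (l < length(layers)) dA * act_grad(cache$Z, spec$activation) else dA
    grads[[l]] <- list(W = dZ %*% t(cache$A_prev), b = rowSums(dZ))
    if (l > 1) dA <- t(layers[[l]]$W) %*% dZ
  }
  nn_flatten(grads)
}

#' Evaluate the embedded network
#'
#' Applies the network's stored input standardization (if any) and runs the
#' forward pass, returning the predicted a4 displacement per row.
#'
#' @param net a `greybox_network` (from [init_network()] or
#'   [train_greybox()]).
#' @param X input matrix with columns `pH, PCO2, FMetHb, T_cel, p`.
#' @return Vector of a4 values, one per row of `X`.
#' @export
network_forward <- function(net, X) {
  X <- as.matrix(X)
  if (any(!is.finite(net$par))) stop("network weights are not finite",
                                     call. = FALSE)
  if (isTRUE(net$log_pressure)) X[, "p"] <- log(X[, "p"])
  Xs <- if (is.null(net$std)) X else standardize_apply(X, net$std)
  nn_forward(net$par, net$spec, Xs)$out
}

#' Grey-box prediction of combined saturation
#'
#' The mechanistic model with the a4 displacement supplied by the embedded
#' network: `sa_predict(..., a4_override = network_forward(net, X))`. With
#' all-zero weights this is exactly the a4 = 0 baseline.
#'
#' @param net a `greybox_network`.
#' @param X input matrix with columns `pH, PCO2, FMetHb, T_cel, p`.
#' @return Vector of combined saturations in (0,1).
#' @export
greybox_predict <- function(net, X) {
  X <- as.matrix(X)
  sa_predict(X[, "pH"], X[, "PCO2"], X[, "FMetHb"],
             T_cel = X[, "T_cel"], p = X[, "p"],
             a4_override = network_forward(net, X))
}

# Per-row quantities of the mechanistic model that do not depend on a4:
# the fixed displacement a1 + a2 + a3 + a5 (FHbF = 0 in the grey box), the
# temperature shift b and the log-pressure coordinate x.
sa_forward_parts <- function(X) {
  cst <- sa_constants()
  a1 <- -0.88 * (X[, "pH"] - 7.40)
  a2 <- 0.048 * log(X[, "PCO2"] / 5.33)
  a3 <- -0.7 * X[, "FMetHb"]
  list(a_fixed = a1 + a2 + a3,
       b = 0.055 * (X[, "T_cel"] - 37),
       x = log(X[, "p"] / cst$p0),
       cst = cst)
}

# Saturation and its analytic sensitivity to the a4 displacement.
sa_from_a4 <- function(parts, a4) {
  cst <- parts$cst
  a <- parts$a_fixed + a4
  x0 <- a + parts$b
  h <- cst$h0 + a
  t <- tanh(cst$k0 * (parts$x - x0))
  y <- cst$y0 + (parts$x - x0) + h * t
  s <- stats::plogis(y)
  dy_da <- t - 1 - h * cst$k0 * (1 - t^2)
  list(s = s, ds_da4 = s * (1 - s) * dy_da)
}

#' MSE loss and gradient of the grey-box model
#'
#' Mean-squared error between grey-box saturations and observations,
#' together with its analytic gradient with respect to the flattened
#' network parameters. The gradient chains the saturation's closed-form
#' sensitivity to a4 into standard backpropagation, so it is exact (up to
#' floating point) for the full composite model.
#'
#' @param par flattened network parameters.
#' @param spec a [network_spec()].
#' @param Xs standardized input matrix.
#' @param parts precomputed [sa_forward_parts()] of the raw inputs.
#' @param s_obs observed combined saturations.
#' @return List with `loss` and `grad`.
#' @export
greybox_loss_grad <- function(par, spec, Xs, parts, s_obs) {
  fwd <- nn_forward(par, spec, Xs)
  sa <- sa_from_a4(parts, fwd$out)
  resid <- sa$s - s_obs
  n <- length(s_obs)
  dout <- 2 / n * resid * sa$ds_da4
  list(loss = mean(resid^2), grad = nn_backward(fwd, spec, dout))
}

#' Training configuration for the grey-box network
#'
#' Two-phase schedule: Adam moves the parameters into a favourable region,
#' then a quasi-Newton (L-BFGS) phase refines to a minimum.
#'
#' @param adam_steps full-batch Adam steps (default 1000).
#' @param adam_lr Adam learning rate (default 1e-3).
#' @param bfgs_max_iters maximum L-BFGS iterations (default 100); a deliberately
#'   modest budget, acting as early stopping so the network does not push
#'   the training MSE far below the observation-noise floor.
#' @param bfgs_tol projected-gradient tolerance (default 1e-9).
#' @param seed integer seed for weight initialization.
#' @param standardize standardize inputs by training mean/SD before the
#'   first layer (default TRUE; the a4 output is not standardized).
#' @param log_pressure feed the network `ln p` rather than raw pressure
#'   (before standardization; default TRUE). The mechanistic model itself
#'   operates in log-pressure coordinates and the sampled pressures are
#'   log-distributed, so this matches the network's input geometry to the
#'   model's and markedly improves generalization off the training points.
#' @return A list of class `training_config`.
#' @export
training_config <- function(adam_steps = 1000, adam_lr = 1e-3,
                            bfgs_max_iters = 100, bfgs_tol = 1e-9,
                            seed = 1L, standardize = TRUE,
                            log_pressure = TRUE) {
  if (adam_steps < 0 || bfgs_max_iters < 0)
    stop("step counts must be non-negative", call. = FALSE)
  if (adam_lr <= 0 || bfgs_tol <= 0)
    stop("learning rate and tolerance must be positive", call. = FALSE)
  structure(list(adam_steps = adam_steps, adam_lr = adam_lr,
                 bfgs_max_iters = bfgs_max_iters, bfgs_tol = bfgs_tol,
                 seed = as.integer(seed), standardize = standardize,
                 log_pressure = log_pressure),
            class = "training_config")
}

#' Train the grey-box model
#'
#' Minimizes the MSE between grey-box predictions and observed combined
#' saturations over the training inputs, with gradients flowing through
#' the full mechanistic composition. Deterministic given the seed.
#'
#' @param X training inputs: matrix with columns `pH, PCO2, FMetHb, T_cel,
#'   p`.
#' @param s_obs observed combined saturations.
#' @param spec a [network_spec()] (default: the 2 x 20 RBF synthetic-study
#'   architecture).
#' @param config a [training_config()].
#' @return A trained `greybox_network` with `loss_trajectory` (per Adam
#'   step, plus the post-L-BFGS value) and `loss_after_adam` recorded.
#' @export
train_greybox <- function(X, s_obs, spec = network_spec(),
                          config = training_config()) {
  X <- as.matrix(X)
  if (nrow(X) == 0) stop("training set is empty", call. = FALSE)
  net <- init_network(spec, seed = config$seed)
  net$log_pressure <- isTRUE(config$log_pressure)
  Xin <- X
  if (net$log_pressure) Xin[, "p"] <- log(Xin[, "p"])
  if (config$standardize) net$std <- standardize_fit(Xin)
  Xs <- if (is.null(net$std)) Xin else standardize_apply(Xin, net$std)
  parts <- sa_forward_parts(X)

  par <- net$par
  m <- v <- numeric(length(par))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  traj <- numeric(config$adam_steps)
  for (step in seq_len(config$adam_steps)) {
    lg <- greybox_loss_grad(par, spec, Xs, parts, s_obs)
    if (!is.finite(lg$loss))
      stop("training diverged (non-finite loss) at Adam step ", step,
           call. = FALSE)
    traj[step] <- lg$loss
    m <- beta1 * m + (1 - beta1) * lg$grad
    v <- beta2 * v + (1 - beta2) * lg$grad^2
    mhat <- m / (1 - beta1^step)
    vhat <- v / (1 - beta2^step)
    par <- par - config$adam_lr * mhat / (sqrt(vhat) + eps)
  }
  loss_after_adam <- greybox_loss_grad(par, spec, Xs, parts, s_obs)$loss

  if (config$bfgs_max_iters > 0) {
    fit <- stats::optim(
      par,
      fn = function(p) greybox_loss_grad(p, spec, Xs, parts, s_obs)$loss,
      gr = function(p) greybox_loss_grad(p, spec, Xs, parts, s_obs)$grad,
      method = "L-BFGS-B",
      control = list(maxit = config$bfgs_max_iters,
                     pgtol = config$bfgs_tol, lmm = 50))
    if (is.finite(fit$value) && fit$value <= loss_after_adam) par <- fit$par
  }
  final_loss <- greybox_loss_grad(par, spec, Xs, parts, s_obs)$loss

  net$par <- par
  net$loss_trajectory <- c(traj, final_loss)
  net$loss_after_adam <- loss_after_adam
  net$final_loss <- final_loss
  net$config <- config
  net
}

#' @export
print.greybox_network <- function(x, ...) {
  cat(sprintf("<greybox_network> %s, hidden [%s], %d parameters\n",
              x$spec$activation, paste(x$spec$hidden, collapse = ", "),
              length(x$par)))
  if (!is.null(x$final_loss))
    cat(sprintf("  trained: final MSE %.3g (after Adam %.3g)\n",
                x$final_loss, x$loss_after_adam))
  invisible(x)
}

#' Export network input/output pairs for symbolic regression
#'
#' The distillation step regresses the trained network's own outputs, not
#' the raw observations: this table is the symbolic-regression training
#' set.
#'
#' @param net a trained `greybox_network`.
#' @param X input matrix (raw scale).
#' @return Data frame with the five input columns and `a4_hat`.
#' @export
export_io_pairs <- function(net, X) {
  X <- as.matrix(X)
  data.frame(X, a4_hat = network_forward(net, X))
}
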