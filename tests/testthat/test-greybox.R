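test_that("zero-weight network reduces the grey box to the baseline model", {
  spec <- network_spec()
  net <- init_network(spec, seed = 1)
  net$par[] <- 0
  X <- make_input_grid(40, seed = 1)
  expect_identical(network_forward(net, X), rep(0, 40))
  expect_identical(greybox_predict(net, X), sa_baseline(X))
})

test_that("single-unit forward pass matches a pencil-and-paper computation", {
  spec <- network_spec(n_inputs = 2, hidden = 1, activation = "rbf")
  net <- init_network(spec, seed = 1)
  # weights: layer 0 (1x2 + bias), layer 1 (1x1 + bias)
  net$par <- c(0.5, -0.3, 0.1, 2.0, -0.7)
  net$std <- NULL
  x <- c(1.2, 0.4)
  z <- 0.5 * 1.2 + (-0.3) * 0.4 + 0.1
  by_hand <- 2.0 * exp(-z^2) + (-0.7)
  X <- matrix(x, 1, dimnames = list(NULL, c("a", "b")))
  expect_equal(network_forward(net, X), by_hand, tolerance = 1e-12)
})

test_that("forward pass is a row-wise map", {
  spec <- network_spec(hidden = c(4, 3))
  net <- init_network(spec, seed = 3)
  X <- make_input_grid(20, seed = 2)
  out <- network_forward(net, X)
  perm <- sample(20)
  expect_equal(network_forward(net, X[perm, ]), out[perm],
               tolerance = 1e-12)
})

test_that("elu activation takes the standard alpha = 1 form", {
  z <- c(-2, -0.5, 0, 0.5, 2)
  expect_equal(odcdisc:::act_fun(z, "elu"),
               ifelse(z > 0, z, exp(z) - 1), tolerance = 1e-15)
  h <- 1e-6
  num <- (odcdisc:::act_fun(z + h, "elu") -
            odcdisc:::act_fun(z - h, "elu")) / (2 * h)
  expect_equal(odcdisc:::act_grad(z, "elu"), num, tolerance = 1e-6)
})

test_that("composite loss gradient matches central finite differences", {
  set.seed(5)
  X <- make_input_grid(5, seed = 5)
  # the network sees standardized inputs, as in training
  Xs <- odcdisc:::standardize_apply(X, odcdisc:::standardize_fit(X))
  s_obs <- runif(5, 0.4, 0.95)
  for (act in c("rbf", "elu")) {
    spec <- network_spec(hidden = c(3, 2), activation = act)
    net <- init_network(spec, seed = 7)
    parts <- odcdisc:::sa_forward_parts(X)
    lg <- greybox_loss_grad(net$par, spec, Xs, parts, s_obs)
    h <- 1e-6
    num <- vapply(seq_along(net$par), function(i) {
      up <- net$par; up[i] <- up[i] + h
      dn <- net$par; dn[i] <- dn[i] - h
      (greybox_loss_grad(up, spec, Xs, parts, s_obs)$loss -
         greybox_loss_grad(dn, spec, Xs, parts, s_obs)$loss) / (2 * h)
    }, numeric(1))
    # relative where the gradient is appreciable, absolute where it is
    # tiny and central differences are noise-dominated
    rel <- max(abs(lg$grad - num) / pmax(abs(num), abs(lg$grad), 1e-6))
    expect_lt(rel, 1e-5)
  }
})

test_that("training is deterministic and the quasi-Newton phase refines Adam", {
  set.seed(6)
  X <- make_input_grid(60, seed = 6)
  s_obs <- sa_predict(X[, "pH"], X[, "PCO2"], X[, "FMetHb"],
                      T_cel = X[, "T_cel"], p = X[, "p"],
                      a4_override = ground_truth_a4(X[, "p"]))
  cfg <- training_config(adam_steps = 100, bfgs_max_iters = 30, seed = 11)
  net1 <- train_greybox(X, s_obs, spec = network_spec(hidden = c(8, 8)),
                        config = cfg)
  net2 <- train_greybox(X, s_obs, spec = network_spec(hidden = c(8, 8)),
                        config = cfg)
  expect_identical(net1$par, net2$par)
  expect_lte(net1$final_loss, net1$loss_after_adam)
  expect_lte(net1$final_loss, net1$loss_trajectory[1])
})

test_that("grey box beats the baseline on a noiseless study", {
  cfg <- synthetic_study_config(seed = 21)
  ds <- generate_dataset(cfg, 0, seed = 21)
  tr <- dataset_partition(ds, "train")
  va <- dataset_partition(ds, "validation")
  net <- train_greybox(tr$X, tr$s_obs,
                       config = training_config(seed = 21))
  expect_lt(rmse(greybox_predict(net, va$X), va$s_true),
            rmse(sa_baseline(va$X), va$s_true))
})

test_that("trained network recovers the hidden displacement at low noise", {
  cors <- vapply(1:5, function(s) recovery_run(0.02, s)$a4_cor_val,
                 numeric(1))
  expect_gt(stats::median(cors), 0.95)
  expect_gt(min(cors), 0.90)
})

test_that("network i/o export has the distillation layout and round-trips", {
  spec <- network_spec(hidden = c(3, 2))
  net <- init_network(spec, seed = 2)
  X <- make_input_grid(15, seed = 3)
  io <- export_io_pairs(net, X)
  expect_equal(dim(io), c(15, 6))
  expect_named(io, c("pH", "PCO2", "FMetHb", "T_cel", "p", "a4_hat"))
  expect_equal(io$a4_hat, network_forward(net, X), tolerance = 1e-15)

  path <- withr::local_tempfile(fileext = ".csv")
  write_io_pairs_csv(io, path)
  back <- read_io_pairs_csv(path)
  expect_equal(as.matrix(back), as.matrix(io), tolerance = 1e-12)

  net$par[] <- 0
  expect_true(all(export_io_pairs(net, X)$a4_hat == 0))
})
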