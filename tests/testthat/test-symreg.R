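test_that("expression evaluation, sizing and string round-trip agree", {
  X <- data.frame(p = c(1, exp(0.5), exp(1), 7),
                  pH = 7.4, PCO2 = 5.33, FMetHb = 0, T_cel = 37)
  expr <- parse_expression("(0.25 * cos(6.2831853 * ln(p))) - 0.55")
  v <- evaluate_expression(expr, X)
  expect_equal(v[1], -0.30, tolerance = 1e-6)
  expect_equal(v[2], -0.80, tolerance = 1e-6)
  expect_equal(v[3], -0.30, tolerance = 1e-6)

  expect_equal(evaluate_expression("p", X), X$p)
  # expression independent of an input is constant along it
  e2 <- parse_expression("sin(pH) + 1")
  expect_equal(length(unique(evaluate_expression(e2, X))), 1L)

  expect_equal(expr_size(parse_expression("p")), 1L)
  expect_equal(expr_size(parse_expression("cos(2 * ln(p))")), 5L)

  s <- expression_to_string(expr, digits = 10)
  expect_equal(evaluate_expression(parse_expression(s), X), v,
               tolerance = 1e-12)
  expect_error(evaluate_expression("q + 1", X), "variable")
})

test_that("protected operators guard domain violations; unprotected flags them", {
  X <- data.frame(p = c(-2, 0, 3))
  expect_true(all(is.finite(evaluate_expression("ln(p)", X))))
  expect_true(all(is.finite(evaluate_expression("1 / p", X))))
  expect_true(all(is.finite(evaluate_expression("exp(p * 100)", X))))
  raw <- suppressWarnings(evaluate_expression("ln(p)", X, protected = FALSE))
  expect_true(is.nan(raw[1]) || is.infinite(raw[1]))
})

test_that("search recovers expressions inside the operator space", {
  set.seed(31)
  X <- data.frame(pH = runif(60, 7, 7.6), PCO2 = runif(60, 3, 9),
                  FMetHb = runif(60, 0, 0.02), T_cel = runif(60, 35, 39),
                  p = exp(runif(60, log(2), log(10))))
  cfg <- sr_config(population = 200, generations = 10, seed = 1)

  # affine target
  fit <- suppressWarnings(fit_symbolic(X, y = 2 * X$pH + 1, config = cfg))
  expect_lt(fit$best_mse, 1e-8)

  # constant target collapses to the constant
  fitc <- suppressWarnings(fit_symbolic(X, y = rep(3.25, 60), config = cfg))
  expect_lt(fitc$best_mse, 1e-10)
  expect_lte(fitc$front$complexity[fitc$front$selected][1], 3)

  # nonlinear in-space target
  fitn <- suppressWarnings(
    fit_symbolic(X, y = sin(X$T_cel) * 0.5 - 1, config = cfg))
  expect_lt(fitn$best_mse, 1e-6)
})

test_that("a larger budget never worsens the best fit under warm start", {
  set.seed(32)
  X <- data.frame(pH = runif(40, 7, 7.6), PCO2 = runif(40, 3, 9),
                  FMetHb = runif(40, 0, 0.02), T_cel = runif(40, 35, 39),
                  p = exp(runif(40, log(2), log(10))))
  y <- 0.3 * log(X$p) * X$pH
  small <- suppressWarnings(fit_symbolic(
    X, y = y, config = sr_config(population = 150, generations = 5, seed = 2)))
  big <- suppressWarnings(fit_symbolic(
    X, y = y, config = sr_config(population = 150, generations = 10, seed = 2),
    warm_start = small))
  expect_lte(big$best_mse, small$best_mse + 1e-15)
})

test_that("canonical cosine-of-log-pressure forms are detected and normalized", {
  m <- match_canonical_form("(0.2476 * cos(6.2762 * ln(p))) - 0.5477")
  expect_equal(m$alpha, 0.2476, tolerance = 1e-6)
  expect_equal(m$beta, 6.2762, tolerance = 1e-6)
  expect_equal(m$gamma, -0.5477, tolerance = 1e-6)
  expect_equal(m$phase, 0, tolerance = 1e-6)

  # phase of pi folds into the amplitude sign
  m2 <- match_canonical_form(
    "(-0.25 * cos((6.2831853 * ln(p)) + 3.14159265)) - 0.55")
  expect_equal(m2$alpha, 0.25, tolerance = 1e-6)
  expect_equal(m2$beta, 2 * pi, tolerance = 1e-6)
  expect_equal(m2$gamma, -0.55, tolerance = 1e-6)

  # sine form is the same family, shifted by a quarter turn
  m3 <- match_canonical_form(
    "(0.25 * sin((6.2831853 * ln(p)) + 1.5707963)) - 0.55")
  expect_equal(m3$alpha, 0.25, tolerance = 1e-5)
  expect_equal(m3$phase, 0, tolerance = 1e-5)

  # structurally different forms are rejected
  expect_null(match_canonical_form("(2 * p) + 1"))
  expect_null(match_canonical_form("(0.2638 * cos(p - 1.4345)) - 0.5659"))
  expect_null(match_canonical_form("0.55"))
  expect_null(match_canonical_form("(0.25 * cos(6.28 * ln(p))) + (0.1 * pH)"))
})

test_that("learned-model predictions compose the expression with the mechanistic model", {
  X <- make_input_grid(30, seed = 33)
  expect_equal(
    learned_model_predict("0 * p", X[1, , drop = FALSE][, , drop = FALSE]),
    sa_baseline(X[1, , drop = FALSE]), tolerance = 1e-12)
  truth <- parse_expression("(0.25 * cos(6.283185307179586 * ln(p))) - 0.55")
  s_truth <- sa_predict(X[, "pH"], X[, "PCO2"], X[, "FMetHb"],
                        T_cel = X[, "T_cel"], p = X[, "p"],
                        a4_override = ground_truth_a4(X[, "p"]))
  expect_equal(learned_model_predict(truth, X), s_truth, tolerance = 1e-9)
})
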