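#' Root-mean-square error
#' @param pred,obs aligned numeric vectors.
#' @return Scalar RMSE.
#' @export
rmse <- function(pred, obs) {
  if (length(pred) != length(obs))
    stop("pred and obs lengths differ", call. = FALSE)
  sqrt(mean((pred - obs)^2))
}

#' k-fold cross-validation split
#'
#' Shuffled, near-equal (sizes differ by at most one), disjoint and
#' exhaustive folds; deterministic given the seed.
#'
#' @param n number of records.
#' @param k fold count (default 10).
#' @param seed integer seed.
#' @return Integer vector of length `n` with fold labels in `1..k`.
#' @export
kfold_split <- function(n, k = 10, seed = 1L) {
  if (n < k) stop("n must be at least k", call. = FALSE)
  set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}

#' Absolute-error summary in SO2 percentage points
#'
#' Converts predictions and observations from the combined-saturation
#' scale to SO2, takes absolute errors in percentage points, and
#' summarizes them with median, quartiles, Tukey whiskers and outliers —
#' the quantities drawn in a box plot.
#'
#' @param s_pred,s_obs predictions and observations on the combined-s
#'   scale.
#' @param FCOHb,FMetHb haemoglobin-variant fractions used in the SO2
#'   conversion (scalars or vectors aligned with the saturations).
#' @return A list of class `error_report` with `errors` (percentage
#'   points), `median`, `q1`, `q3`, `whisker_low`, `whisker_high`,
#'   `outliers`.
#' @export
absolute_error_report <- function(s_pred, s_obs, FCOHb = 0, FMetHb = 0) {
  if (length(s_pred) != length(s_obs))
    stop("prediction and observation lengths differ", call. = FALSE)
  err <- abs(saturation_to_so2(s_pred, FCOHb, FMetHb) -
               saturation_to_so2(s_obs, FCOHb, FMetHb)) * 100
  qs <- stats::quantile(err, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- qs[3] - qs[1]
  lo_fence <- qs[1] - 1.5 * iqr
  hi_fence <- qs[3] + 1.5 * iqr
  inside <- err >= lo_fence & err <= hi_fence
  structure(list(errors = err, median = qs[2], q1 = qs[1], q3 = qs[3],
                 whisker_low = if (any(inside)) min(err[inside]) else NA_real_,
                 whisker_high = if (any(inside)) max(err[inside]) else NA_real_,
                 outliers = err[!inside]),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf(
    "<error_report> median %.2f [IQR %.2f-%.2f] %%-points, %d outliers\n",
    x$median, x$q1, x$q3, length(x$outliers)))
  invisible(x)
}

#' Min-max normalization
#'
#' Used to normalize predictive standard deviations for scatter coloring.
#'
#' @param x numeric vector.
#' @return `x` rescaled to \[0,1\]; all-equal input maps to 0.
#' @export
minmax_normalize <- function(x) {
  r <- range(x)
  if (diff(r) == 0) return(rep(0, length(x)))
  (x - r[1]) / diff(r)
}

#' Run the synthetic recovery study
#'
#' For each noise level: generate the synthetic dataset, fit the
#' constrained-GP discrepancy model, train the grey-box network, distill
#' it by symbolic regression, and evaluate all models on the validation
#' partition. Stage seeds derive from the configuration seed (dataset:
#' `seed`; GP and network: `seed + 1`; distillation: `seed + 2`), the
#' same wiring as the staged analysis scripts, so the orchestrated and
#' staged routes produce identical fits.
#'
#' @param config a [synthetic_study_config()].
#' @param noise_levels noise levels to run (default: those in `config`).
#' @param nn_spec grey-box [network_spec()].
#' @param train_cfg grey-box [training_config()] (its seed is overridden by
#'   the derived sub-seed).
#' @param sr_cfg symbolic-regression [sr_config()] (seed likewise derived).
#' @param gp_starts multi-start count for the GP MAP fit.
#' @param fit_gp fit the GP discrepancy model (TRUE) or skip it.
#' @param fit_sr run the symbolic-regression distillation (TRUE) or skip.
#' @return A list of class `synthetic_study` with one entry per noise
#'   level (dataset, fitted models, validation RMSEs, learned expression
#'   and canonical-form match) plus a `summary` data frame.
#' @export
run_synthetic_study <- function(config = synthetic_study_config(),
                                noise_levels = config$noise_levels,
                                nn_spec = network_spec(),
                                train_cfg = training_config(),
                                sr_cfg = sr_config(),
                                gp_starts = 6,
                                fit_gp = TRUE, fit_sr = TRUE) {
  results <- list()
  for (i in seq_along(noise_levels)) {
    nl <- noise_levels[i]
    ds <- generate_dataset(config, nl, seed = config$seed)
    tr <- dataset_partition(ds, "train")
    va <- dataset_partition(ds, "validation")

    res <- list(noise_level = nl, dataset = ds)
    res$rmse_baseline <- rmse(sa_baseline(va$X), va$s_true)

    if (fit_gp) {
      gp <- fit_gp_discrepancy(tr$X, tr$s_obs, n_starts = gp_starts,
                               seed = config$seed + 1L)
      pr <- gp_predict(gp, va$X)
      res$gp <- gp
      res$gp_val <- pr
      res$rmse_gp <- rmse(pr$mean, va$s_true)
    }

    tc <- train_cfg; tc$seed <- config$seed + 1L
    net <- train_greybox(tr$X, tr$s_obs, spec = nn_spec, config = tc)
    res$net <- net
    res$rmse_greybox <- rmse(greybox_predict(net, va$X), va$s_true)
    res$a4_cor <- stats::cor(network_forward(net, va$X),
                             ground_truth_a4(va$X[, "p"]))

    if (fit_sr) {
      io <- export_io_pairs(net, tr$X)
      sc <- sr_cfg; sc$seed <- config$seed + 2L
      sr <- fit_symbolic(io, operators = operator_set(), config = sc)
      res$sr <- sr
      res$expression <- expression_to_string(sr$best)
      res$canonical <- match_canonical_form(sr$best)
      res$rmse_learned <- rmse(learned_model_predict(sr$best, va$X),
                               va$s_true)
    }
    results[[i]] <- res
  }

  summary <- do.call(rbind, lapply(results, function(r) {
    data.frame(
      noise_level = r$noise_level,
      rmse_baseline = r$rmse_baseline,
      rmse_gp = if (is.null(r$rmse_gp)) NA_real_ else r$rmse_gp,
      rmse_greybox = r$rmse_greybox,
      rmse_learned = if (is.null(r$rmse_learned)) NA_real_ else r$rmse_learned,
      a4_cor = r$a4_cor,
      expression = if (is.null(r$expression)) NA_character_ else r$expression,
      canonical_match = !is.null(r$canonical))
  }))

  structure(list(results = results, summary = summary, config = config),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("<synthetic_study>\n")
  print(x$summary, digits = 4)
  invisible(x)
}

#' Per-patient ODC comparison across fitted models
#'
#' For one record, sweeps each fitted model's ODC over a pressure grid
#' with the record's other inputs held fixed, and collects the predicted
#' SO2 at the record's own pressure. The GP bundle carries a +/- 2 SD
#' band.
#'
#' @param record a one-row input (named vector, one-row matrix or data
#'   frame) with entries `pH, PCO2, FMetHb, T_cel, p`.
#' @param gp optional fitted [fit_gp_discrepancy()] model.
#' @param net optional trained `greybox_network`.
#' @param expr optional learned expression (tree or string).
#' @param p_grid pressure grid, kPa (default 200 log-spaced points on
#'   \[0.5, 45\]).
#' @param FCOHb carboxyhaemoglobin fraction for SO2 conversion.
#' @return A list of class `odc_comparison` with `curves` (long data
#'   frame: model, p, s, SO2, and for the GP `s_lo`/`s_hi`) and `points`
#'   (predicted SO2 of each model at the record's pressure).
#' @export
patient_odc_comparison <- function(record, gp = NULL, net = NULL,
                                   expr = NULL,
                                   p_grid = exp(seq(log(0.5), log(45),
                                                    length.out = 200)),
                                   FCOHb = 0) {
  rec <- as.data.frame(as.list(unlist(record)))
  need <- c("pH", "PCO2", "FMetHb", "T_cel", "p")
  if (!all(need %in% names(rec)))
    stop("record must provide ", paste(need, collapse = ", "), call. = FALSE)
  grid_X <- cbind(pH = rep(rec$pH, length(p_grid)), PCO2 = rec$PCO2,
                  FMetHb = rec$FMetHb, T_cel = rec$T_cel, p = p_grid)
  point_X <- grid_X[1, , drop = FALSE]
  point_X[, "p"] <- rec$p

  curves <- list()
  points <- list()
  to_so2 <- function(s) unname(saturation_to_so2(s, FCOHb, rec$FMetHb))

  s_base <- sa_baseline(grid_X)
  curves$baseline <- data.frame(model = "baseline", p = p_grid, s = s_base,
                                SO2 = to_so2(s_base))
  points$baseline <- to_so2(sa_baseline(point_X))

  if (!is.null(gp)) {
    pr <- gp_predict(gp, grid_X)
    curves$gp <- data.frame(model = "gp", p = p_grid, s = pr$mean,
                            SO2 = to_so2(pr$mean),
                            s_lo = pr$mean - 2 * pr$sd,
                            s_hi = pr$mean + 2 * pr$sd)
    points$gp <- to_so2(gp_predict(gp, point_X)$mean)
  }
  if (!is.null(net)) {
    s_nn <- greybox_predict(net, grid_X)
    curves$greybox <- data.frame(model = "greybox", p = p_grid, s = s_nn,
                                 SO2 = to_so2(s_nn))
    points$greybox <- to_so2(greybox_predict(net, point_X))
  }
  if (!is.null(expr)) {
    s_lm <- learned_model_predict(expr, grid_X)
    curves$learned <- data.frame(model = "learned", p = p_grid, s = s_lm,
                                 SO2 = to_so2(s_lm))
    points$learned <- to_so2(learned_model_predict(expr, point_X))
  }

  structure(list(curves = curves, points = points, record = rec),
            class = "odc_comparison")
}
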