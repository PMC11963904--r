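#!/usr/bin/env Rscript
# Stage 4: distillation. Genetic-programming symbolic regression over
# unary {sin, cos, ln, exp} and binary {+, -, /, *} fits the trained
# network's input/output pairs; the selected expression becomes the a4
# term of the "learned model". Reads the stage-3 tables, writes ranked
# expression tables and a per-noise-level summary with canonical-form
# coefficients where the cosine-of-ln-p structure is recovered.

suppressMessages(library(odcdisc))

seed <- 1L
cfg <- synthetic_study_config(seed = seed)
dir.create("results", showWarnings = FALSE)

rows <- list()
for (nl in cfg$noise_levels) {
  io_path <- sprintf("results/nn_io_noise%02d.csv", round(100 * nl))
  if (!file.exists(io_path))
    stop(io_path, " missing; run analysis/03_fit_greybox.R first")
  io <- read_io_pairs_csv(io_path)
  sr <- suppressWarnings(
    fit_symbolic(io, config = sr_config(seed = seed + 2L)))
  write_expression_table(
    sr, sprintf("results/expressions_noise%02d.csv", round(100 * nl)))
  can <- match_canonical_form(sr$best)

  ds <- generate_dataset(cfg, nl, seed = seed)
  va <- dataset_partition(ds, "validation")
  rows[[length(rows) + 1]] <- data.frame(
    noise_level = nl,
    expression = expression_to_string(sr$best),
    sr_mse = sr$best_mse,
    rmse_learned = rmse(learned_model_predict(sr$best, va$X), va$s_true),
    alpha = if (is.null(can)) NA_real_ else can$alpha,
    beta = if (is.null(can)) NA_real_ else can$beta,
    gamma = if (is.null(can)) NA_real_ else can$gamma)
  message(sprintf("noise %2.0f%%: %s", 100 * nl,
                  expression_to_string(sr$best)))
  if (!is.null(can))
    message(sprintf("   canonical: %.4f * cos(%.4f ln p) %+.4f   (truth 0.25 * cos(6.2832 ln p) - 0.55)",
                    can$alpha, can$beta, can$gamma))
}
utils::write.csv(do.call(rbind, rows), "results/learned_expressions.csv",
                 row.names = FALSE)
message("\nresults/learned_expressions.csv summarizes the learned forms per noise level.")
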