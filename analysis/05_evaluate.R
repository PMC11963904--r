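#!/usr/bin/env Rscript
# Stage 5: model comparison. Re-runs the full study through
# run_synthetic_study() (all three corrections per noise level), writes
# the summary table, absolute-error reports in SO2 percentage points, and
# a per-patient ODC curve bundle for one validation record, plus a
# machine-readable JSON summary.

suppressMessages(library(odcdisc))

seed <- 1L
dir.create("results", showWarnings = FALSE)
study <- suppressWarnings(
  run_synthetic_study(synthetic_study_config(seed = seed)))
print(study)
utils::write.csv(study$summary, "results/study_summary.csv",
                 row.names = FALSE)

# absolute errors in SO2 percentage points on the validation split
err_rows <- list()
for (r in study$results) {
  va <- dataset_partition(r$dataset, "validation")
  models <- list(baseline = sa_baseline(va$X),
                 gp = r$gp_val$mean,
                 greybox = greybox_predict(r$net, va$X),
                 learned = learned_model_predict(r$sr$best, va$X))
  for (nm in names(models)) {
    rep <- absolute_error_report(models[[nm]], va$s_true)
    err_rows[[length(err_rows) + 1]] <- data.frame(
      noise_level = r$noise_level, model = nm, median = rep$median,
      q1 = rep$q1, q3 = rep$q3, whisker_low = rep$whisker_low,
      whisker_high = rep$whisker_high, n_outliers = length(rep$outliers))
  }
}
err <- do.call(rbind, err_rows)
utils::write.csv(err, "results/absolute_errors_so2.csv", row.names = FALSE)
message("\nMedian absolute error (SO2 %-points) by model and noise level:")
print(reshape(err[c("noise_level", "model", "median")],
              idvar = "noise_level", timevar = "model",
              direction = "wide"), row.names = FALSE)

# showcase patient: largest baseline improvement by the learned model
r5 <- study$results[[2]]  # 5% noise panel
va <- dataset_partition(r5$dataset, "validation")
imp <- abs(sa_baseline(va$X) - va$s_true) -
  abs(learned_model_predict(r5$sr$best, va$X) - va$s_true)
best_i <- which.max(imp)
cmp <- patient_odc_comparison(va$X[best_i, ], gp = r5$gp, net = r5$net,
                              expr = r5$sr$best)
curves <- do.call(rbind, lapply(cmp$curves, function(d) {
  d$s_lo <- if ("s_lo" %in% names(d)) d$s_lo else NA_real_
  d$s_hi <- if ("s_hi" %in% names(d)) d$s_hi else NA_real_
  d
}))
utils::write.csv(curves, "results/patient_odc_curves.csv",
                 row.names = FALSE)
message(sprintf(
  "\nShowcase patient (5%% noise, record %d): observed s %.3f; predicted SO2 baseline %.1f%%, gp %.1f%%, greybox %.1f%%, learned %.1f%%",
  best_i, va$s_obs[best_i], 100 * cmp$points$baseline,
  100 * cmp$points$gp, 100 * cmp$points$greybox, 100 * cmp$points$learned))

if (requireNamespace("jsonlite", quietly = TRUE)) {
  jsonlite::write_json(
    list(summary = study$summary, absolute_errors = err),
    "results/study_summary.json", dataframe = "rows", digits = NA)
  message("JSON summary: results/study_summary.json")
}
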