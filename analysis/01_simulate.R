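#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study datasets.
#
# The ground truth is the mechanistic ODC model with a hidden oscillatory
# 2,3-DPG displacement a4(p) = 0.25 cos(2 pi ln p) - 0.55. Observations
# add Gaussian noise at 2/5/10/15% of the SD of the noiseless targets;
# 200 training and 50 validation points per noise level; no low-saturation
# samples (arterial regime). Writes one CSV per noise level under
# results/.

suppressMessages(library(odcdisc))

seed <- 1L
dir.create("results", showWarnings = FALSE)
cfg <- synthetic_study_config(seed = seed)

for (nl in cfg$noise_levels) {
  ds <- generate_dataset(cfg, nl, seed = seed)
  path <- sprintf("results/dataset_noise%02d.csv", round(100 * nl))
  write_dataset_csv(ds, path)
  base_rmse <- rmse(sa_baseline(ds$X), ds$s_true)
  resid <- ds$s_obs - sa_baseline(ds$X)
  message(sprintf(
    "noise %2.0f%%: sd(s_true) %.3f, noise sd %.4f, baseline RMSE %.3f, mean residual %+.3f -> %s",
    100 * nl, sd(ds$s_true), ds$noise_sd, base_rmse, mean(resid), path))
}

message("\nThe positive mean residuals show the a4 = 0 model systematically")
message("underestimates saturation under the hidden displacement.")
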