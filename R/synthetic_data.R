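#' Hidden ground-truth a4 displacement
#'
#' The oscillatory 2,3-DPG displacement used as ground truth in the
#' synthetic recovery study: `a4(p) = 0.25 * cos(2 * pi * ln(p)) - 0.55`,
#' periodic in `ln p` with angular frequency `2 * pi` and range
#' \[-0.80, -0.30\]. Being everywhere negative it shifts the ODC so that a
#' model with a4 = 0 systematically underestimates saturation.
#'
#' @param p combined partial pressure, kPa; positive.
#' @return a4 displacement, unitless.
#' @export
#' @examples
#' ground_truth_a4(1)  # -0.30
ground_truth_a4 <- function(p) {
  if (any(p <= 0)) stop("p must be positive", call. = FALSE)
  0.25 * cos(2 * pi * log(p)) - 0.55
}

#' Configuration of the synthetic recovery study
#'
#' Study conditions for the synthetic ground-truth experiment: 200 training
#' and 50 validation points, additive Gaussian noise at 2/5/10/15% of the
#' standard deviation of the noiseless targets, and rejection of draws whose
#' noiseless combined saturation falls below `low_s_cutoff` (mimicking the
#' clinical reality that low-saturation arterial samples are rare).
#'
#' Input sampling ranges are clinically plausible arterial values: pH
#' uniform on (7.0, 7.6), PCO2 uniform on (3, 9) kPa, FMetHb uniform on
#' (0, 0.02), temperature uniform on (35, 39) C, and `ln p` uniform on
#' (ln 2, ln 10). The pressure range is chosen so that the noiseless
#' saturations span roughly 0.4-1.0 with real spread (the data regime of
#' the study this emulates) and so that most observations remain
#' informative about a4: above ~10 kPa the curve is flat at s near 1 and
#' the displacement has vanishing effect on the observable, so samples
#' there identify nothing.
#'
#' @param n_train number of training points (default 200).
#' @param n_val number of validation points (default 50).
#' @param noise_levels noise standard deviations as fractions of the SD of
#'   the noiseless targets (default `c(0.02, 0.05, 0.10, 0.15)`).
#' @param seed integer seed making every generated dataset reproducible.
#' @param low_s_cutoff minimum noiseless combined saturation retained
#'   (default 0.35); set 0 to disable rejection.
#' @param ranges named list of length-2 numeric ranges for `pH`, `PCO2`,
#'   `FMetHb`, `T_cel` and `log_p`.
#' @return A list of class `synthetic_study_config`.
#' @export
synthetic_study_config <- function(n_train = 200, n_val = 50,
                                   noise_levels = c(0.02, 0.05, 0.10, 0.15),
                                   seed = 1L,
                                   low_s_cutoff = 0.35,
                                   ranges = list(
                                     pH = c(7.0, 7.6),
                                     PCO2 = c(3, 9),
                                     FMetHb = c(0, 0.02),
                                     T_cel = c(35, 39),
                                     log_p = log(c(2, 10))
                                   )) {
  if (n_train <= 0 || n_val <= 0)
    stop("n_train and n_val must be positive", call. = FALSE)
  if (any(noise_levels < 0))
    stop("noise levels must be non-negative", call. = FALSE)
  structure(list(n_train = as.integer(n_train), n_val = as.integer(n_val),
                 noise_levels = noise_levels, seed = as.integer(seed),
                 low_s_cutoff = low_s_cutoff, ranges = ranges),
            class = "synthetic_study_config")
}

#' Sample physiological input points
#'
#' Draws `n` rows of (pH, PCO2, FMetHb, T, p) from the configured uniform
#' ranges (`p` log-uniform) and rejection-resamples any row whose noiseless
#' ground-truth saturation falls below the low-s cutoff. Deterministic given
#' the seed.
#'
#' @param config a [synthetic_study_config()].
#' @param n number of rows.
#' @param seed integer seed (defaults to `config$seed`).
#' @return An `n x 5` matrix with columns `pH, PCO2, FMetHb, T_cel, p`.
#' @export
sample_inputs <- function(config, n, seed = config$seed) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  set.seed(seed)
  rg <- config$ranges
  draw <- function(m) {
    cbind(pH = stats::runif(m, rg$pH[1], rg$pH[2]),
          PCO2 = stats::runif(m, rg$PCO2[1], rg$PCO2[2]),
          FMetHb = stats::runif(m, rg$FMetHb[1], rg$FMetHb[2]),
          T_cel = stats::runif(m, rg$T_cel[1], rg$T_cel[2]),
          p = exp(stats::runif(m, rg$log_p[1], rg$log_p[2])))
  }
  X <- matrix(numeric(0), ncol = 5)
  colnames(X) <- c("pH", "PCO2", "FMetHb", "T_cel", "p")
  attempts <- 0L
  drawn <- 0L
  while (nrow(X) < n) {
    batch <- draw(max(n, 64L))
    s <- sa_predict(batch[, "pH"], batch[, "PCO2"], batch[, "FMetHb"],
                    T_cel = batch[, "T_cel"], p = batch[, "p"],
                    a4_override = ground_truth_a4(batch[, "p"]))
    keep <- s >= config$low_s_cutoff
    attempts <- attempts + nrow(batch)
    drawn <- drawn + sum(keep)
    X <- rbind(X, batch[keep, , drop = FALSE])
    if (attempts > 100L * n && drawn < attempts / 100)
      stop("rejection rate above 99%; check low_s_cutoff and input ranges",
           call. = FALSE)
  }
  X[seq_len(n), , drop = FALSE]
}

#' Generate one synthetic dataset
#'
#' Samples training + validation inputs, evaluates the ground-truth model
#' (the mechanistic ODC with the hidden oscillatory a4), and adds Gaussian
#' observation noise with standard deviation `noise_level` times the SD of
#' the noiseless targets over the generated set. Noisy saturations are
#' clipped into \[1e-3, 1 - 1e-3\]. Pure function of `(config, noise_level,
#' seed)`.
#'
#' @param config a [synthetic_study_config()].
#' @param noise_level noise SD as a fraction of SD of the noiseless targets.
#' @param seed integer seed (defaults to `config$seed`).
#' @return A list of class `synthetic_dataset` with elements `X` (inputs),
#'   `s_true`, `s_obs`, `a4_true`, `noise_sd`, `noise_level` and `split`
#'   (factor `"train"`/`"validation"`).
#' @export
generate_dataset <- function(config, noise_level, seed = config$seed) {
  n <- config$n_train + config$n_val
  X <- sample_inputs(config, n, seed = seed)
  a4 <- ground_truth_a4(X[, "p"])
  s_true <- sa_predict(X[, "pH"], X[, "PCO2"], X[, "FMetHb"],
                       T_cel = X[, "T_cel"], p = X[, "p"], a4_override = a4)
  noise_sd <- noise_level * stats::sd(s_true)
  # continue the stream seeded inside sample_inputs; one draw per row
  eps <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else numeric(n)
  s_obs <- pmin(pmax(s_true + eps, 1e-3), 1 - 1e-3)
  split <- factor(rep(c("train", "validation"),
                      c(config$n_train, config$n_val)),
                  levels = c("train", "validation"))
  structure(list(X = X, s_true = s_true, s_obs = s_obs, a4_true = a4,
                 noise_sd = noise_sd, noise_level = noise_level,
                 split = split, seed = as.integer(seed)),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset> %d train + %d validation points, noise %.0f%% (sd %.4f on s)\n",
    sum(x$split == "train"), sum(x$split == "validation"),
    100 * x$noise_level, x$noise_sd))
  invisible(x)
}

#' Split helpers for synthetic datasets
#'
#' @param dataset a [generate_dataset()] result.
#' @param which `"train"` or `"validation"`.
#' @return A list with `X`, `s_true`, `s_obs`, `a4_true` restricted to the
#'   requested partition.
#' @export
dataset_partition <- function(dataset, which = c("train", "validation")) {
  which <- match.arg(which)
  i <- dataset$split == which
  list(X = dataset$X[i, , drop = FALSE], s_true = dataset$s_true[i],
       s_obs = dataset$s_obs[i], a4_true = dataset$a4_true[i])
}
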