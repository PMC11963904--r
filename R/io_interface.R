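#' Read blood-gas records from CSV
#'
#' Expects columns `pH`, `PCO2` (kPa), `T` (degrees C; `T_cel` also
#' accepted), `pO2` (kPa), `SO2`, `FCOHb`, `FMetHb`; `FHbF` is optional
#' and defaults to 0. Saturations and haemoglobin fractions may be given
#' as fractions or percentages — any column whose maximum exceeds 1.5 is
#' treated as percent and divided by 100. Rows with missing temperature
#' are dropped with a message, mirroring the retention rule used with
#' analyzer exports where temperature is not always recorded.
#'
#' @param path CSV file path.
#' @return A [blood_gas_record()] data frame.
#' @export
read_blood_gas_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  if ("T" %in% names(df) && !"T_cel" %in% names(df))
    names(df)[names(df) == "T"] <- "T_cel"
  mandatory <- c("pH", "PCO2", "T_cel", "pO2", "SO2", "FCOHb", "FMetHb")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols) > 0)
    stop("missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!"FHbF" %in% names(df)) df$FHbF <- 0

  n0 <- nrow(df)
  df <- df[!is.na(df$T_cel), , drop = FALSE]
  dropped <- n0 - nrow(df)
  if (dropped > 0)
    message(dropped, " record(s) dropped for missing temperature")

  for (col in c("SO2", "FCOHb", "FMetHb", "FHbF")) {
    v <- df[[col]]
    if (any(v > 1.5, na.rm = TRUE)) df[[col]] <- v / 100
  }
  blood_gas_record(df$pH, df$PCO2, df$T_cel, df$pO2, df$SO2,
                   df$FCOHb, df$FMetHb, df$FHbF,
                   cDPG = if ("cDPG" %in% names(df)) df$cDPG else 5)
}

#' Write blood-gas records to CSV
#'
#' Writes fractions (not percentages) with a `T` temperature column, the
#' layout [read_blood_gas_csv()] reads back.
#'
#' @param records a [blood_gas_record()] data frame.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_blood_gas_csv <- function(records, path) {
  out <- as.data.frame(records)
  names(out)[names(out) == "T_cel"] <- "T"
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic dataset to CSV
#'
#' Columns: `pH, PCO2, FMetHb, T, p, s_obs, s_true, a4_true, split`.
#'
#' @param dataset a [generate_dataset()] result.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(dataset, path) {
  out <- data.frame(dataset$X, s_obs = dataset$s_obs,
                    s_true = dataset$s_true, a4_true = dataset$a4_true,
                    split = as.character(dataset$split))
  names(out)[names(out) == "T_cel"] <- "T"
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a synthetic dataset from CSV
#'
#' Inverse of [write_dataset_csv()].
#'
#' @param path CSV path.
#' @return A list of class `synthetic_dataset` (without the generating
#'   noise metadata, which is not stored in the file beyond the values
#'   themselves).
#' @export
read_dataset_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  names(df)[names(df) == "T"] <- "T_cel"
  need <- c("pH", "PCO2", "FMetHb", "T_cel", "p", "s_obs", "s_true",
            "a4_true", "split")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  X <- as.matrix(df[c("pH", "PCO2", "FMetHb", "T_cel", "p")])
  structure(list(X = X, s_true = df$s_true, s_obs = df$s_obs,
                 a4_true = df$a4_true, noise_sd = NA_real_,
                 noise_level = NA_real_,
                 split = factor(df$split,
                                levels = c("train", "validation")),
                 seed = NA_integer_),
            class = "synthetic_dataset")
}

#' Write the network input/output table for distillation
#'
#' @param io_pairs data frame from [export_io_pairs()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_io_pairs_csv <- function(io_pairs, path) {
  utils::write.csv(io_pairs, path, row.names = FALSE)
  invisible(path)
}

#' Read a network input/output table
#' @param path CSV path written by [write_io_pairs_csv()].
#' @return Data frame with the input columns and `a4_hat`.
#' @export
read_io_pairs_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  if (!"a4_hat" %in% names(df))
    stop("missing a4_hat column", call. = FALSE)
  df
}

#' Write a ranked expression table
#'
#' Serializes a symbolic-regression front as CSV with columns
#' `expression`, `mse`, `complexity`, `selected`; expressions are infix
#' strings that [parse_expression()] round-trips.
#'
#' @param fit an `sr_fit`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(fit, path) {
  utils::write.csv(
    fit$front[c("expression", "mse", "complexity", "selected")],
    path, row.names = FALSE)
  invisible(path)
}
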