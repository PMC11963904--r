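#' Siggaard-Andersen ODC model constants
#'
#' Fixed constants of the Siggaard-Andersen oxygen dissociation curve model:
#' the tanh Hill-plot slope constant, the reference point of the curve, and
#' the reference physiological conditions for adult humans. The reference
#' logit `y0 = ln(s0/(1 - s0))` is derived from `s0` at call time so the
#' saturation constant has a single source of truth.
#'
#' @return A named list with elements `k0` (slope constant, 0.5343), `s0`
#'   (reference combined saturation, 0.867), `p0` (reference combined partial
#'   pressure, 7 kPa), `h0` (reference Hill amplitude, 3.5), `y0` (derived
#'   reference logit), and the reference conditions `pH_ref` (7.40),
#'   `PCO2_ref` (5.33 kPa), `cDPG_ref` (5 mmol/L), `T_ref` (37 degrees C).
#' @export
#' @examples
#' sa_constants()$s0
sa_constants <- function() {
  s0 <- 0.867
  list(
    k0 = 0.5343,
    s0 = s0,
    p0 = 7,
    h0 = 3.5,
    y0 = log(s0 / (1 - s0)),
    pH_ref = 7.40,
    PCO2_ref = 5.33,
    cDPG_ref = 5,
    T_ref = 37
  )
}

#' Construct blood-gas records
#'
#' Bundles one or more patient blood-gas measurements into a validated
#' data frame. Saturations and haemoglobin fractions are stored as fractions
#' in (0,1); pressures in kPa; temperature in degrees Celsius.
#'
#' @param pH blood acidity (unitless).
#' @param PCO2 partial pressure of carbon dioxide, kPa; must be positive.
#' @param T_cel body temperature, degrees Celsius.
#' @param pO2 partial pressure of oxygen, kPa; must be positive.
#' @param SO2 haemoglobin oxygen saturation, fraction in (0,1).
#' @param FCOHb carboxyhaemoglobin fraction in \[0,1).
#' @param FMetHb methaemoglobin fraction in \[0,1).
#' @param FHbF foetal haemoglobin fraction in \[0,1); defaults to 0
#'   (negligible and rarely recorded for adults).
#' @param cDPG 2,3-diphosphoglycerate concentration, mmol/L; defaults to the
#'   reference 5 mmol/L.
#' @return A data frame of class `blood_gas_record` with one row per record.
#' @export
blood_gas_record <- function(pH, PCO2, T_cel, pO2, SO2,
                             FCOHb = 0, FMetHb = 0, FHbF = 0, cDPG = 5) {
  rec <- data.frame(pH = pH, PCO2 = PCO2, T_cel = T_cel, pO2 = pO2,
                    SO2 = SO2, FCOHb = FCOHb, FMetHb = FMetHb,
                    FHbF = FHbF, cDPG = cDPG)
  if (any(rec$SO2 <= 0 | rec$SO2 >= 1))
    stop("SO2 must lie strictly in (0, 1)", call. = FALSE)
  if (any(rec$FCOHb + rec$FMetHb >= 1))
    stop("FCOHb + FMetHb must be < 1", call. = FALSE)
  if (any(rec$pO2 <= 0)) stop("pO2 must be positive", call. = FALSE)
  if (any(rec$PCO2 <= 0)) stop("PCO2 must be positive", call. = FALSE)
  class(rec) <- c("blood_gas_record", "data.frame")
  rec
}

#' Combined partial pressure of oxygen and carbon monoxide
#'
#' Maps a measured oxygen partial pressure onto the combined O2 + CO
#' partial-pressure coordinate in which the Siggaard-Andersen Hill plot is a
#' line plus tanh term. With no carboxyhaemoglobin the combined pressure is
#' just `pO2`.
#'
#' @param pO2 oxygen partial pressure, kPa.
#' @param SO2 oxygen saturation, fraction; must be positive.
#' @param FCOHb,FMetHb carboxy- and methaemoglobin fractions.
#' @return Combined partial pressure p, kPa; always `>= pO2`.
#' @export
#' @examples
#' combined_partial_pressure(10, 0.8, 0.05, 0.01)
combined_partial_pressure <- function(pO2, SO2, FCOHb = 0, FMetHb = 0) {
  if (any(SO2 <= 0))
    stop("SO2 must be positive to form the combined pressure", call. = FALSE)
  if (any(FCOHb + FMetHb >= 1))
    stop("FCOHb + FMetHb must be < 1", call. = FALSE)
  pO2 + (pO2 / SO2) * FCOHb / (1 - FCOHb - FMetHb)
}

#' Combined saturation of oxygen and carbon monoxide
#'
#' @param SO2 oxygen saturation, fraction.
#' @param FCOHb,FMetHb carboxy- and methaemoglobin fractions.
#' @return Combined saturation s, fraction in \[0,1\].
#' @export
#' @examples
#' combined_saturation(0.9, 0.05, 0.01)
combined_saturation <- function(SO2, FCOHb = 0, FMetHb = 0) {
  if (any(FMetHb >= 1))
    stop("FMetHb must be < 1", call. = FALSE)
  (SO2 * (1 - FCOHb - FMetHb) + FCOHb) / (1 - FMetHb)
}

#' Convert combined saturation back to oxygen saturation
#'
#' Inverse of [combined_saturation()]; used when reporting model predictions
#' (made on the combined-saturation scale) as clinical SO2 values.
#'
#' @param s combined saturation, fraction.
#' @param FCOHb,FMetHb carboxy- and methaemoglobin fractions.
#' @return Oxygen saturation SO2, fraction.
#' @export
saturation_to_so2 <- function(s, FCOHb = 0, FMetHb = 0) {
  if (any(1 - FCOHb - FMetHb <= 0))
    stop("FCOHb + FMetHb must be < 1", call. = FALSE)
  (s * (1 - FMetHb) - FCOHb) / (1 - FCOHb - FMetHb)
}

#' ODC displacement decomposition
#'
#' Computes the five displacement contributions that shift the oxygen
#' dissociation curve away from its reference position at 37 degrees C:
#' acidity (a1), carbon dioxide (a2), methaemoglobin (a3), 2,3-DPG (a4) and
#' foetal haemoglobin (a5). The "unknown knowns" term a6 is fixed at zero in
#' every pipeline path; `a4_override` replaces the 2,3-DPG formula and is the
#' hook through which the grey-box network, the learned symbolic expression
#' and the synthetic ground truth enter the model.
#'
#' @param pH blood acidity.
#' @param PCO2 carbon dioxide partial pressure, kPa; positive.
#' @param FMetHb methaemoglobin fraction.
#' @param FHbF foetal haemoglobin fraction (default 0).
#' @param cDPG 2,3-DPG concentration, mmol/L (default 5, the reference).
#' @param a4_override optional replacement for the a4 term (unitless
#'   displacement); vector recycled against the other inputs.
#' @return A list of class `displacement_terms` with components `a1`..`a6`,
#'   `ac` (= a1+...+a5) and `a` (= ac + a6). All elements are vectors of the
#'   common input length.
#' @export
#' @examples
#' displacement_ac(7.20, 5.33, 0)$a1  # 0.176
displacement_ac <- function(pH, PCO2, FMetHb = 0, FHbF = 0, cDPG = 5,
                            a4_override = NULL) {
  if (any(PCO2 <= 0)) stop("PCO2 must be positive", call. = FALSE)
  a1 <- -0.88 * (pH - 7.40)
  a2 <- 0.048 * log(PCO2 / 5.33)
  a3 <- -0.7 * FMetHb
  a4 <- if (is.null(a4_override)) {
    (0.3 - 0.1 * FHbF) * (cDPG / 5 - 1)
  } else {
    a4_override
  }
  a5 <- -0.25 * FHbF
  terms <- list(a1 = a1, a2 = a2, a3 = a3, a4 = a4, a5 = a5, a6 = 0)
  terms$ac <- a1 + a2 + a3 + a4 + a5
  terms$a <- terms$ac + terms$a6
  class(terms) <- "displacement_terms"
  terms
}

#' Forward evaluation of the ODC
#'
#' The Siggaard-Andersen curve in Hill-plot coordinates:
#' `y - y0 = (x - x0) + h * tanh(k0 * (x - x0))` with `x = ln(p/p0)`,
#' `x0 = a + b`, `h = h0 + a` and the temperature displacement
#' `b = 0.055 * (T - 37)`. Returns the combined saturation
#' `s = 1/(1 + exp(-y))`. Strictly increasing in `p` whenever `h > 0`.
#'
#' @param p combined partial pressure, kPa; positive.
#' @param a total displacement at 37 C (unitless).
#' @param T_cel temperature, degrees Celsius.
#' @return Combined saturation s, fraction in (0,1).
#' @export
#' @examples
#' odc_forward(7, 0, 37)  # reference saturation 0.867
odc_forward <- function(p, a = 0, T_cel = 37) {
  if (any(p <= 0)) stop("p must be positive", call. = FALSE)
  cst <- sa_constants()
  x <- log(p / cst$p0)
  b <- 0.055 * (T_cel - 37)
  x0 <- a + b
  h <- cst$h0 + a
  y <- cst$y0 + (x - x0) + h * tanh(cst$k0 * (x - x0))
  stats::plogis(y)
}

#' Predict combined saturation from physiological inputs
#'
#' Composes [displacement_ac()] and [odc_forward()]: the full mechanistic
#' model from (pH, PCO2, FMetHb, T, p) to combined saturation s. This is the
#' baseline `f(x)` of the discrepancy analyses when `a4_override = 0`, and
#' the grey-box / learned model when `a4_override` carries the network or
#' symbolic a4.
#'
#' @param pH,PCO2,FMetHb,FHbF,cDPG displacement inputs; see
#'   [displacement_ac()].
#' @param T_cel temperature, degrees Celsius.
#' @param p combined partial pressure, kPa.
#' @param a4_override optional replacement for the a4 term.
#' @return Combined saturation s, fraction in (0,1).
#' @export
#' @examples
#' sa_predict(7.40, 5.33, 0, T_cel = 37, p = 7, a4_override = 0)  # 0.867
sa_predict <- function(pH, PCO2, FMetHb = 0, FHbF = 0, cDPG = 5,
                       T_cel = 37, p, a4_override = NULL) {
  dt <- displacement_ac(pH, PCO2, FMetHb, FHbF, cDPG, a4_override)
  odc_forward(p, dt$a, T_cel)
}

#' Sweep an oxygen dissociation curve over a pressure grid
#'
#' Holds the displacement inputs fixed and evaluates the model along a grid
#' of combined partial pressures, optionally with a per-point a4 supplied by
#' a provider function (e.g. the synthetic ground truth, a trained network
#' wrapper or a learned expression). Returns the curve both on the
#' combined-saturation scale and converted to SO2.
#'
#' @param pH,PCO2,FMetHb,FHbF,cDPG,T_cel fixed physiological inputs.
#' @param FCOHb carboxyhaemoglobin fraction, used only for the SO2
#'   conversion of the curve (default 0).
#' @param p_grid increasing vector of positive combined pressures, kPa.
#' @param a4_provider `NULL` for the cDPG formula, a single number for a
#'   constant override, or a function of the n x 5 input matrix
#'   (pH, PCO2, FMetHb, T, p) returning a4 values.
#' @return A data frame with columns `p`, `s`, `SO2`.
#' @export
odc_curve <- function(pH, PCO2, FMetHb = 0, FHbF = 0, cDPG = 5, T_cel = 37,
                      FCOHb = 0, p_grid, a4_provider = NULL) {
  if (length(p_grid) == 0) stop("p_grid must be non-empty", call. = FALSE)
  if (any(p_grid <= 0)) stop("p_grid must be positive", call. = FALSE)
  if (is.unsorted(p_grid, strictly = TRUE))
    stop("p_grid must be strictly increasing", call. = FALSE)
  a4 <- if (is.null(a4_provider)) {
    NULL
  } else if (is.function(a4_provider)) {
    X <- cbind(pH = rep(pH, length(p_grid)), PCO2 = PCO2, FMetHb = FMetHb,
               T_cel = T_cel, p = p_grid)
    a4_provider(X)
  } else {
    a4_provider
  }
  s <- sa_predict(pH, PCO2, FMetHb, FHbF, cDPG, T_cel, p_grid,
                  a4_override = a4)
  data.frame(p = p_grid, s = s,
             SO2 = saturation_to_so2(s, FCOHb, FMetHb))
}
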