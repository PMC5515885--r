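## Fitting and inverting the concentration -> A/D calibration.

#' Fit the linear-with-floor quench calibration
#'
#' Least-squares fit of `A/D(C) = ratioAtZero * max(1 - slope*C, floor)`
#' to observed (concentration, ratio) pairs.  `ratioAtZero` is a free
#' parameter (absolute A/D depends on the instrument) and the floor is held
#' at its configured value.  The fit is initialized from an ordinary linear
#' regression on the sub-floor segment and refined with
#' Levenberg-Marquardt least squares.  If the data are incompatible with a
#' non-increasing calibration (fitted slope below zero, or residual RMS
#' above `residualThreshold`), the returned curve carries a non-monotone
#' warning flag; the stored slope is clamped at zero so the predicted curve
#' always satisfies the monotonicity invariant.
#'
#' @param pairs data.frame with columns `concentration` (mg/mL) and
#'   `ratio` (A/D), or a two-column matrix.
#' @param floor fixed saturation floor of the quench model.
#' @param residualThreshold residual RMS (as a fraction of the fitted
#'   `ratioAtZero`) above which the non-monotone/misfit flag is raised.
#' @return A [CalibrationCurve-class].
#' @examples
#' C <- c(0, 2, 5, 10)
#' pairs <- data.frame(concentration = C,
#'                     ratio = 1.2 * quenchFactor(C))
#' fitCalibration(pairs)
#' @export
fitCalibration <- function(pairs, floor = 0.2, residualThreshold = 0.05) {
  pairs <- as.data.frame(pairs)
  if (!all(c("concentration", "ratio") %in% names(pairs)))
    names(pairs)[1:2] <- c("concentration", "ratio")
  C <- as.numeric(pairs$concentration)
  r <- as.numeric(pairs$ratio)
  if (length(unique(C)) < 3L)
    stop(npcError("npcCalibrationError",
                  "need at least 3 distinct concentrations"))
  if (any(C < 0) || any(r <= 0))
    stop(npcError("npcCalibrationError",
                  "concentrations must be >= 0 and ratios > 0"))

  ## linear initialization: r = a + b*C on the (assumed) linear segment
  ini <- stats::lm(r ~ C)
  r0.ini <- max(stats::coef(ini)[1], min(r), 1e-6)
  s.ini <- max(-stats::coef(ini)[2] / r0.ini, 0)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      r ~ r0 * pmax(1 - s * C, floor),
      start = list(r0 = r0.ini, s = s.ini),
      lower = c(r0 = 1e-9, s = -1),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)

  if (is.null(fit)) {
    r0 <- r0.ini; s <- s.ini
  } else {
    cf <- stats::coef(fit)
    r0 <- unname(cf["r0"]); s <- unname(cf["s"])
  }

  pred <- r0 * pmax(1 - max(s, 0) * C, floor)
  rms <- sqrt(mean((r - pred)^2))
  flag <- s <= 0 && stats::var(r) > 0 && stats::cor(C, r) > 0
  flag <- flag || rms > residualThreshold * r0

  new("CalibrationCurve",
      ratioAtZero = r0,
      slope = max(s, 0),
      floor = floor,
      fittedOn = data.frame(concentration = C, ratio = r),
      residualRms = rms,
      nonMonotoneFlag = isTRUE(flag))
}

#' Predict A/D from a fitted calibration
#'
#' @param curve a [CalibrationCurve-class].
#' @param C concentration(s) in mg/mL.
#' @return Predicted A/D ratio(s).
#' @export
predictRatio <- function(curve, C) {
  stopifnot(is(curve, "CalibrationCurve"))
  curve@ratioAtZero * quenchFactor(C, curve@slope, curve@floor)
}

#' Invert a fitted calibration to a concentration estimate
#'
#' Unique inverse of the monotone linear segment: ratios are invertible on
#' `(ratioAtZero * floor, ratioAtZero]`.  A ratio outside this range
#' signals a saturation error of class `npcSaturationError` whose
#' `boundary` field carries the concentration at the violated boundary
#' (0 above the range; the floor-onset concentration below it).
#'
#' @param ratio observed A/D ratio.
#' @param curve a [CalibrationCurve-class].
#' @return Concentration estimate in mg/mL.
#' @examples
#' curve <- fitCalibration(data.frame(
#'   concentration = c(0, 50, 100, 200),
#'   ratio = 1.2 * quenchFactor(c(0, 50, 100, 200))))
#' invertCalibration(1.2 * 0.8, curve)  # 100 mg/mL
#' @export
invertCalibration <- function(ratio, curve) {
  stopifnot(is(curve, "CalibrationCurve"), length(ratio) == 1L)
  r0 <- curve@ratioAtZero
  if (curve@slope <= 0)
    stop(npcError("npcSaturationError",
                  "calibration has zero slope; not invertible",
                  boundary = 0))
  cFloor <- (1 - curve@floor) / curve@slope
  if (ratio > r0)
    stop(npcError("npcSaturationError", sprintf(
      "ratio %.4g above ratioAtZero %.4g; estimate saturates at C = 0",
      ratio, r0), boundary = 0))
  if (ratio <= r0 * curve@floor)
    stop(npcError("npcSaturationError", sprintf(
      "ratio %.4g at or below the floor segment (%.4g); estimate saturates at C = %.4g mg/mL",
      ratio, r0 * curve@floor, cFloor), boundary = cFloor))
  (1 - ratio / r0) / curve@slope
}
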