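## Generics and simple accessors / show methods.

#' @describeIn EmissionSpectrum-class wavelength grid accessor
#' @param object an object.
#' @export
setGeneric("wavelength", function(object) standardGeneric("wavelength"))

#' @describeIn EmissionSpectrum-class intensity accessor
#' @export
setGeneric("intensity", function(object) standardGeneric("intensity"))

#' @export
#' @rdname EmissionSpectrum-class
setMethod("wavelength", "EmissionSpectrum", function(object) object@wavelength)

#' @export
#' @rdname EmissionSpectrum-class
setMethod("intensity", "EmissionSpectrum", function(object) object@intensity)

setMethod("show", "EmissionSpectrum", function(object) {
  wl <- object@wavelength
  cat(sprintf(
    "EmissionSpectrum '%s': %d samples, %.0f-%.0f nm (step %.3g nm), ex %.0f nm\n",
    object@label, length(wl), min(wl), max(wl),
    if (length(wl) > 1) wl[2] - wl[1] else NA_real_, object@excitation))
})

#' Region label accessor
#'
#' @param object an object carrying region labels.
#' @return For [RegionMasks-class], the integer label matrix.
#' @export
setGeneric("regionLabels", function(object) standardGeneric("regionLabels"))

#' @rdname regionLabels
#' @export
setMethod("regionLabels", "RegionMasks", function(object) object@labels)

#' Extract a logical region mask
#'
#' @param object a [RegionMasks-class].
#' @param region one of "background", "cytoplasm", "nucleus", "rim".
#' @return logical matrix.
#' @export
setGeneric("regionMask", function(object, region) standardGeneric("regionMask"))

#' @rdname regionMask
#' @export
setMethod("regionMask", "RegionMasks", function(object, region) {
  code <- match(match.arg(region,
                          c("background", "cytoplasm", "nucleus", "rim")),
                c("background", "cytoplasm", "nucleus", "rim")) - 1L
  object@labels == code
})

setMethod("show", "RegionMasks", function(object) {
  tab <- table(factor(object@labels, levels = 0:3,
                      labels = c("background", "cytoplasm", "nucleus", "rim")))
  cat(sprintf("RegionMasks %dx%d (rim width %g px)\n",
              nrow(object@labels), ncol(object@labels), object@rimWidth))
  print(tab)
})

setMethod("show", "CalibrationCurve", function(object) {
  cat(sprintf(
    "CalibrationCurve: A/D(C) = %.4g * max(1 - %.4g*C, %.3g)\n",
    object@ratioAtZero, object@slope, object@floor))
  cat(sprintf("  fitted on %d pairs, residual RMS %.4g%s\n",
              nrow(object@fittedOn), object@residualRms,
              if (object@nonMonotoneFlag) "  [non-monotone data flag]" else ""))
})

setMethod("show", "CellMeasurement", function(object) {
  cat(sprintf(
    "CellMeasurement '%s': probeNE %.4f, probeCyto %.4f, relative %.4f%s\n",
    object@cellId, object@probeNE, object@probeCyto, object@relativeProbe,
    if (length(object@qcFlags))
      paste0("  [", paste(object@qcFlags, collapse = ","), "]") else ""))
})

setMethod("show", "GroupSummary", function(object) {
  cat(sprintf(
    "GroupSummary '%s' (n=%d): mean %.4f +/- %.4f; median %.4f [Q1 %.4f, Q3 %.4f]; %d outlier(s)\n",
    object@label, object@n, object@mean, object@sd, object@median,
    object@q1, object@q3, length(object@outliers)))
})

setMethod("show", "TreatmentComparison", function(object) {
  cat(sprintf(
    "TreatmentComparison %s vs %s: relative mean %.4f; Welch t = %.4g, df = %.3g, p = %.4g\n",
    object@treatedLabel, object@referenceLabel, object@relativeMean,
    object@tStatistic, object@df, object@pValue))
})

setMethod("show", "TimelapseTrace", function(object) {
  cat(sprintf(
    "TimelapseTrace: %d frames, t = %.1f..%.1f min (onset frame %d)\n",
    length(object@times), min(object@times), max(object@times),
    object@onsetFrame))
  if (length(object@halfTimes))
    for (nm in names(object@halfTimes)) {
      ht <- object@halfTimes[[nm]]
      cat(sprintf("  %s half-time: %s min\n", nm,
                  if (ht@recoverable) sprintf("%.2f", ht@time) else "n.d."))
    }
})

setMethod("show", "HalfTimeResult", function(object) {
  cat(sprintf("HalfTimeResult (%s): %s (level %.4g, %s)\n",
              object@direction,
              if (object@recoverable) sprintf("%.3f min", object@time)
              else "unrecoverable",
              object@level, object@method))
})

setMethod("show", "PhantomManifest", function(object) {
  cat(sprintf("PhantomManifest [%s]", object@kind))
  if (!is.null(object@config) && length(object@config@preset))
    cat(sprintf(" preset '%s'", object@config@preset))
  cat("\n  expected:", paste(names(object@expected), collapse = ", "), "\n")
})

#' Expected (ground-truth) quantities of a phantom
#'
#' @param object a [PhantomManifest-class].
#' @return Named list of analytically expected read-outs.
#' @export
setGeneric("expectedValues", function(object) standardGeneric("expectedValues"))

#' @rdname expectedValues
#' @export
setMethod("expectedValues", "PhantomManifest", function(object) object@expected)

#' Ground-truth region masks of a phantom
#'
#' @param object a [PhantomManifest-class].
#' @param frame frame index for time-lapse manifests (ignored otherwise).
#' @return A [RegionMasks-class] built from the manifest labels.
#' @export
setGeneric("manifestMasks",
           function(object, frame = 1L) standardGeneric("manifestMasks"))

#' @rdname manifestMasks
#' @export
setMethod("manifestMasks", "PhantomManifest", function(object, frame = 1L) {
  lab <- if (is.list(object@labels)) object@labels[[frame]] else object@labels
  new("RegionMasks", labels = lab, rimWidth = object@config@rimWidth)
})
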