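## Per-cell ratiometric quantification of interphase images.

#' Region probe signal (A/D) from an image pair
#'
#' Ratio of background-subtracted region means:
#' `(mean acceptor - bgAcceptor) / (mean donor - bgDonor)` over the mask.
#' The convention is ratio-of-means, not mean-of-pixel-ratios, which is
#' robust to low-intensity pixels.  Supplying the true background makes
#' the statistic exactly invariant to a constant offset added to both
#' channels.
#'
#' @param acceptor,donor numeric matrices (counts).
#' @param mask logical matrix selecting the region.
#' @param bgAcceptor,bgDonor per-channel background estimates (counts).
#' @param epsilon smallest admissible background-subtracted donor mean.
#' @return Dimensionless A/D ratio.
#' @export
probeSignal <- function(acceptor, donor, mask, bgAcceptor = 0,
                        bgDonor = 0, epsilon = 1e-6) {
  if (!any(mask))
    stop(npcError("npcRegionError", "empty region mask"))
  dden <- mean(donor[mask]) - bgDonor
  if (dden <= epsilon)
    stop(npcError("npcUndefinedRatioError", sprintf(
      "background-subtracted donor mean %.4g <= epsilon %.4g", dden,
      epsilon)))
  (mean(acceptor[mask]) - bgAcceptor) / dden
}

#' Measure one cell
#'
#' Populates a [CellMeasurement-class] from a donor/acceptor image pair
#' and region masks: probe signal at the nuclear envelope and in the
#' cytoplasm, their ratio (`relativeProbe`), and background-subtracted
#' donor localization intensities.  Backgrounds default to per-channel
#' estimates from the background mask (see [estimateBackground()]); the
#' true values can be supplied for noise-free validation.
#'
#' @param donor,acceptor numeric matrices (counts).
#' @param masks a [RegionMasks-class].
#' @param background optional list with elements `donor` and `acceptor`;
#'   `NULL` to estimate from the background mask.
#' @param cellId identifier stored in the result.
#' @param minRegionPx QC threshold: regions smaller than this raise a
#'   `small-region` flag.
#' @return A [CellMeasurement-class].
#' @examples
#' ph <- simulateInterphaseCell(cellPhantomConfig("peripheral",
#'                                                noise = "none"))
#' m <- measureCell(ph$donor, ph$acceptor, manifestMasks(ph$manifest),
#'                  background = list(donor = 100, acceptor = 100))
#' m@relativeProbe  # ~0.75
#' @export
measureCell <- function(donor, acceptor, masks, background = NULL,
                        cellId = "cell", minRegionPx = 50) {
  stopifnot(is(masks, "RegionMasks"))
  rim <- regionMask(masks, "rim")
  cyto <- regionMask(masks, "cytoplasm")
  if (is.null(background))
    background <- list(donor = estimateBackground(donor, masks),
                       acceptor = estimateBackground(acceptor, masks))
  qc <- character()
  for (nm in c("rim", "cytoplasm", "nucleus"))
    if (sum(regionMask(masks, nm)) < minRegionPx)
      qc <- c(qc, paste0("small-region:", nm))

  pNE <- probeSignal(acceptor, donor, rim, background$acceptor,
                     background$donor)
  pCy <- probeSignal(acceptor, donor, cyto, background$acceptor,
                     background$donor)
  new("CellMeasurement",
      cellId = cellId,
      probeNE = pNE, probeCyto = pCy,
      relativeProbe = pNE / pCy,
      localizationNE = mean(donor[rim]) - background$donor,
      localizationCyto = mean(donor[cyto]) - background$donor,
      qcFlags = qc)
}

#' Per-cell measurements as a data.frame
#'
#' @param measurements list of [CellMeasurement-class] objects.
#' @return data.frame with one row per cell.
#' @export
measurementTable <- function(measurements) {
  do.call(rbind, lapply(measurements, function(m) data.frame(
    cell_id = m@cellId,
    probe_ne = m@probeNE,
    probe_cyto = m@probeCyto,
    relative_probe = m@relativeProbe,
    localization_ne = m@localizationNE,
    localization_cyto = m@localizationCyto,
    qc = paste(m@qcFlags, collapse = ";"),
    stringsAsFactors = FALSE)))
}

#' Summarize a group of per-cell values
#'
#' Mean and SD (n-1 denominator), median, quartiles with the
#' linear-interpolation convention (`stats::quantile` type 7) and outliers
#' beyond 1.5*IQR from the quartiles, matching the boxplot presentation
#' used for treatment comparisons.
#'
#' @param x numeric vector, or a list of [CellMeasurement-class] objects.
#' @param statistic which measurement field to summarize when `x` is a
#'   list of measurements.
#' @param label group label.
#' @return A [GroupSummary-class].
#' @examples
#' summarizeGroup(c(1, 2, 3, 4, 5))
#' @export
summarizeGroup <- function(x, statistic = c("relativeProbe", "probeNE",
                                            "probeCyto"),
                           label = "group") {
  statistic <- match.arg(statistic)
  if (is.list(x) && length(x) && is(x[[1]], "CellMeasurement"))
    x <- vapply(x, function(m) slot(m, statistic), numeric(1))
  x <- as.numeric(x)
  if (!length(x))
    stop(npcError("npcStatsError", "need at least one value"))
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  out <- x[x < q[1] - 1.5 * iqr | x > q[3] + 1.5 * iqr]
  new("GroupSummary", label = label, n = length(x),
      mean = mean(x),
      sd = if (length(x) > 1L) stats::sd(x) else NA_real_,
      median = q[2], q1 = q[1], q3 = q[3], outliers = out)
}

#' Expression-independence control
#'
#' Regresses the per-cell relative probe signal on the donor rim
#' localization intensity (ordinary least squares) and reports the slope
#' and Pearson correlation.  A crowding read-out independent of probe
#' expression level should show negligible correlation; the function
#' reports only and makes no test decision.
#'
#' @param measurements list of [CellMeasurement-class] objects (n >= 5).
#' @return List with `slope`, `correlation`, `n`.
#' @export
expressionIndependenceCheck <- function(measurements) {
  if (length(measurements) < 5L)
    stop(npcError("npcStatsError",
                  "need at least 5 cells with varying localization"))
  rel <- vapply(measurements, function(m) m@relativeProbe, numeric(1))
  loc <- vapply(measurements, function(m) m@localizationNE, numeric(1))
  if (stats::var(loc) == 0)
    stop(npcError("npcStatsError",
                  "localization has zero variance; slope undefined"))
  fit <- stats::lm(rel ~ loc)
  list(slope = unname(stats::coef(fit)[2]),
       correlation = if (stats::var(rel) == 0) 0 else
         stats::cor(loc, rel),
       n = length(rel))
}

#' Compare a treated group against a reference group
#'
#' Treated per-cell probe signals (`probeNE`) are normalized to the
#' reference group mean (the "relative to intact cells" convention) and
#' the groups are compared with a two-tailed Welch t-test on the
#' unnormalized values.
#'
#' @param reference,treated lists of [CellMeasurement-class] objects, or
#'   numeric vectors of probe signals.
#' @param referenceLabel,treatedLabel group labels.
#' @return A [TreatmentComparison-class].
#' @export
compareTreatments <- function(reference, treated,
                              referenceLabel = "intact",
                              treatedLabel = "treated") {
  asVals <- function(x) {
    if (is.list(x) && length(x) && is(x[[1]], "CellMeasurement"))
      vapply(x, function(m) m@probeNE, numeric(1))
    else as.numeric(x)
  }
  refv <- asVals(reference); trtv <- asVals(treated)
  if (!length(refv) || !length(trtv))
    stop(npcError("npcStatsError", "both groups must be non-empty"))
  wt <- welchTTest(refv, trtv)
  rel <- trtv / mean(refv)
  new("TreatmentComparison",
      referenceLabel = referenceLabel, treatedLabel = treatedLabel,
      relativeValues = rel, relativeMean = mean(rel),
      tStatistic = wt$t, df = wt$df, pValue = wt$p,
      referenceSummary = summarizeGroup(refv / mean(refv),
                                        label = referenceLabel),
      treatedSummary = summarizeGroup(rel, label = treatedLabel))
}
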