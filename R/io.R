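## File formats: spectrum CSV, multichannel TIFF, JSON sidecars.

#' Read an emission spectrum from CSV
#'
#' Expects a header and columns `wavelength_nm,intensity`, one spectrum
#' per file.
#'
#' @param path CSV file path.
#' @param label label to attach (defaults to the file name).
#' @param excitation excitation wavelength (nm).
#' @return An [EmissionSpectrum-class].
#' @export
readSpectrumCsv <- function(path, label = basename(path),
                            excitation = 433) {
  df <- utils::read.csv(path)
  if (!all(c("wavelength_nm", "intensity") %in% names(df)))
    stop(npcError("npcIOError",
                  "spectrum CSV needs columns wavelength_nm,intensity"))
  EmissionSpectrum(df$wavelength_nm, df$intensity,
                   excitation = excitation, label = label)
}

#' Write an emission spectrum to CSV
#'
#' @param spectrum an [EmissionSpectrum-class].
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeSpectrumCsv <- function(spectrum, path) {
  utils::write.csv(data.frame(wavelength_nm = spectrum@wavelength,
                              intensity = spectrum@intensity),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a spectrum batch manifest
#'
#' CSV with columns `file,label,concentration_mg_per_ml`; file paths are
#' resolved relative to the manifest location.
#'
#' @param path manifest CSV path.
#' @return data.frame with a `spectrum` list-column of
#'   [EmissionSpectrum-class] objects.
#' @export
readSpectrumManifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("file", "label", "concentration_mg_per_ml")
  if (!all(need %in% names(df)))
    stop(npcError("npcIOError", paste(
      "spectrum manifest needs columns", paste(need, collapse = ","))))
  if (!nrow(df))
    stop(npcError("npcIOError", "empty spectrum manifest"))
  dir <- dirname(path)
  df$spectrum <- lapply(seq_len(nrow(df)), function(i) {
    f <- df$file[i]
    if (!file.exists(f)) f <- file.path(dir, f)
    readSpectrumCsv(f, label = df$label[i])
  })
  df
}

#' Write a fitted calibration to JSON
#'
#' @param curve a [CalibrationCurve-class].
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeCalibrationJson <- function(curve, path) {
  jsonlite::write_json(list(
    model = "linear-with-floor",
    ratio_at_zero = curve@ratioAtZero,
    slope_per_mg_ml = curve@slope,
    floor = curve@floor,
    residual_rms = curve@residualRms,
    non_monotone_flag = curve@nonMonotoneFlag,
    pairs = curve@fittedOn
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a calibration from JSON
#'
#' @param path JSON path written by [writeCalibrationJson()].
#' @return A [CalibrationCurve-class].
#' @export
readCalibrationJson <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("CalibrationCurve",
      ratioAtZero = j$ratio_at_zero, slope = j$slope_per_mg_ml,
      floor = j$floor,
      fittedOn = as.data.frame(j$pairs),
      residualRms = j$residual_rms,
      nonMonotoneFlag = isTRUE(j$non_monotone_flag))
}

## TIFF pages hold counts / .tiffScale as 32-bit floats; the scale is
## recorded in the JSON sidecar so counts round-trip.
.tiffScale <- 65535

#' Write an image stack as a multipage float TIFF
#'
#' Channels/frames become TIFF pages; count values are stored divided by
#' a fixed scale (65535) recorded in any accompanying manifest.
#'
#' @param images a matrix, a list of matrices, or a 3-d array.
#' @param path output TIFF path.
#' @return The path, invisibly.
#' @export
writeImageStack <- function(images, path) {
  if (is.array(images) && length(dim(images)) == 3L)
    images <- lapply(seq_len(dim(images)[3]), function(i) images[, , i])
  if (is.matrix(images)) images <- list(images)
  tiff::writeTIFF(lapply(images, function(m) m / .tiffScale), path,
                  bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Read an image stack written by [writeImageStack()]
#'
#' @param path TIFF path.
#' @return List of count matrices (one per page).
#' @export
readImageStack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  lapply(pages, function(m) m * .tiffScale)
}

#' Write a phantom manifest as JSON plus label-mask TIFF
#'
#' The JSON sidecar carries the expected values, configuration and
#' intensity scale; ground-truth label masks go to a single-channel
#' integer TIFF next to it (`<path>.labels.tif`).
#'
#' @param manifest a [PhantomManifest-class].
#' @param path output JSON path.
#' @return The path, invisibly.
#' @export
writeManifestJson <- function(manifest, path) {
  cfg <- manifest@config
  cfgList <- if (!is.null(cfg)) {
    nms <- slotNames(class(cfg))
    stats::setNames(lapply(nms, function(s) slot(cfg, s)), nms)
  } else NULL
  jsonlite::write_json(list(
    kind = manifest@kind,
    expected = manifest@expected,
    config = cfgList,
    intensity_scale = .tiffScale,
    labels_file = paste0(basename(path), ".labels.tif")
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  labs <- manifest@labels
  if (is.matrix(labs)) labs <- list(labs)
  if (is.list(labs) && length(labs) && is.matrix(labs[[1]]))
    tiff::writeTIFF(lapply(labs, function(m) m / 255),
                    paste0(path, ".labels.tif"), bits.per.sample = 8L)
  invisible(path)
}

#' Write per-cell measurements to CSV
#'
#' Columns: `cell_id,probe_ne,probe_cyto,relative_probe,localization_ne,`
#' `localization_cyto,qc`.  Probe values are always background-subtracted.
#'
#' @param measurements list of [CellMeasurement-class] objects.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
writeCellCsv <- function(measurements, path) {
  utils::write.csv(measurementTable(measurements), path,
                   row.names = FALSE)
  invisible(path)
}

#' Write a time-lapse trace to CSV and its half-times to JSON
#'
#' The per-frame CSV has columns `t_min,localization,probe,area`; the
#' JSON carries the extracted half-times and the extraction convention.
#'
#' @param trace a [TimelapseTrace-class].
#' @param csvPath per-frame CSV path.
#' @param jsonPath half-time JSON path (`NULL` to skip).
#' @return `csvPath`, invisibly.
#' @export
writeTraceCsv <- function(trace, csvPath, jsonPath = NULL) {
  utils::write.csv(data.frame(
    t_min = trace@times,
    localization = trace@localization,
    probe = trace@probe,
    area = trace@area), csvPath, row.names = FALSE)
  if (!is.null(jsonPath)) {
    ht <- lapply(trace@halfTimes, function(h) list(
      time_min = if (h@recoverable) h@time else NA,
      direction = h@direction, level = h@level,
      recoverable = h@recoverable, method = h@method))
    jsonlite::write_json(list(onset_frame = trace@onsetFrame,
                              half_times = ht,
                              qc = trace@qcFlags),
                         jsonPath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(csvPath)
}
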