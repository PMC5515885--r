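## Batch entry points tying generation, calibration and quantification
## together.  These back the thin command-line wrapper in
## inst/scripts/npcrowd-cli.R; the functions themselves are the API.

.resolveConfigArgs <- function(configFile, overrides) {
  base <- if (!is.null(configFile)) yaml::read_yaml(configFile) else list()
  for (nm in names(overrides)) base[[nm]] <- overrides[[nm]]
  base
}

#' Generate a batch of synthetic datasets on disk
#'
#' Writes TIFF images plus JSON manifests for `n` phantoms of the
#' requested kind into `outDir`.  Per-phantom seeds are derived
#' deterministically from `seed` (seed, seed+1, ...), so a fixed
#' seed/config pair reproduces the batch bit-for-bit.
#'
#' @param kind "spectra", "cells", "timelapse" or "immunostain".
#' @param preset preset name (see [phantomPresets()]); `NULL` for
#'   defaults.
#' @param n number of phantoms (cells/immunostain) or concentrations
#'   (spectra).
#' @param seed base RNG seed.
#' @param outDir output directory (created if missing).
#' @param configFile optional YAML file of configuration overrides; any
#'   `...` argument takes precedence over the file.
#' @param ... configuration overrides passed to the phantom constructor.
#' @return Character vector of the primary files written, invisibly.
#' @export
runSimulate <- function(kind = c("cells", "timelapse", "immunostain",
                                 "spectra"),
                        preset = NULL, n = 1L, seed = 1L,
                        outDir = ".", configFile = NULL, ...) {
  kind <- match.arg(kind)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  args <- .resolveConfigArgs(configFile, list(...))
  out <- character()

  if (kind == "spectra") {
    conc <- if (!is.null(args$concentrations))
      unlist(args$concentrations) else c(0, 2, 5, 10)
    rows <- lapply(seq_along(conc), function(i) {
      sp <- simulateSpectrum("GimRET", C = conc[i],
                             noiseSd = args$noiseSd %||% 0,
                             seed = seed + i)
      f <- file.path(outDir, sprintf("spectrum_C%03g.csv", conc[i]))
      writeSpectrumCsv(sp, f)
      data.frame(file = basename(f), label = sp@label,
                 concentration_mg_per_ml = conc[i])
    })
    mf <- file.path(outDir, "spectra_manifest.csv")
    utils::write.csv(do.call(rbind, rows), mf, row.names = FALSE)
    return(invisible(mf))
  }

  if (kind == "cells") {
    for (i in seq_len(n)) {
      cfgArgs <- c(list(preset = preset, seed = seed + i - 1L),
                   args[names(args) %in% names(formals(cellPhantomConfig))])
      cfg <- do.call(cellPhantomConfig, cfgArgs)
      ph <- simulateInterphaseCell(cfg)
      stem <- file.path(outDir, sprintf("cell_%03d", i))
      writeImageStack(list(ph$donor, ph$acceptor),
                      paste0(stem, ".tif"))
      writeManifestJson(ph$manifest, paste0(stem, ".manifest.json"))
      out <- c(out, paste0(stem, ".tif"))
    }
    return(invisible(out))
  }

  if (kind == "immunostain") {
    pre <- .immunostainPresets[[preset %||% "digitonin_immunostain"]]
    if (is.null(pre))
      stop(npcError("npcConfigError",
                    sprintf("unknown immunostain preset '%s'", preset)))
    retention <- args$retention %||% pre$retention
    for (i in seq_len(n)) {
      cfg <- cellPhantomConfig(seed = seed + i - 1L,
                               densityCyto = pre$densityCyto,
                               densityNucleus = pre$densityNucleus,
                               densityRim = pre$densityRim)
      pr <- simulateImmunostainPair(retention, cfg)
      stem <- file.path(outDir, sprintf("immunostain_%03d", i))
      writeImageStack(list(pr$intact, pr$treated), paste0(stem, ".tif"))
      writeManifestJson(pr$manifest, paste0(stem, ".manifest.json"))
      out <- c(out, paste0(stem, ".tif"))
    }
    return(invisible(out))
  }

  ## timelapse
  cfgArgs <- c(list(preset = preset, seed = seed),
               args[names(args) %in%
                    names(formals(timelapsePhantomConfig))])
  cfg <- do.call(timelapsePhantomConfig, cfgArgs)
  tl <- simulateTimelapse(cfg)
  stem <- file.path(outDir, "timelapse")
  nf <- dim(tl$donor)[3]
  pages <- unlist(lapply(seq_len(nf), function(i)
    list(tl$donor[, , i], tl$acceptor[, , i], tl$chromosome[, , i])),
    recursive = FALSE)
  writeImageStack(pages, paste0(stem, ".tif"))
  writeManifestJson(tl$manifest, paste0(stem, ".manifest.json"))
  invisible(paste0(stem, ".tif"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Quantify a directory of interphase phantoms
#'
#' Reads every two-page donor/acceptor TIFF in `dir`, segments the donor
#' channel, measures each cell and writes a per-cell CSV plus a group
#' summary.  Per-cell failures are flagged and skipped; the batch
#' continues.
#'
#' @param dir input directory (output of `runSimulate("cells", ...)`).
#' @param outCsv per-cell CSV path (`NULL` for `<dir>/cells.csv`).
#' @param rimWidth rim band width used for segmentation.
#' @return List with `measurements`, `summary` ([GroupSummary-class]) and
#'   `failures` (character).
#' @export
runQuantifyInterphase <- function(dir, outCsv = NULL, rimWidth = 3) {
  tifs <- sort(list.files(dir, pattern = "^cell_[0-9]+\\.tif$",
                          full.names = TRUE))
  if (!length(tifs))
    stop(npcError("npcIOError", sprintf("no cell TIFFs in %s", dir)))
  measurements <- list(); failures <- character()
  for (f in tifs) {
    m <- tryCatch({
      pages <- readImageStack(f)
      masks <- segmentCell(pages[[1]], rimWidth = rimWidth)
      measureCell(pages[[1]], pages[[2]], masks,
                  cellId = sub("\\.tif$", "", basename(f)))
    }, error = function(e) {
      warning(sprintf("skipping %s: %s", basename(f),
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (is.null(m)) failures <- c(failures, basename(f))
    else measurements <- c(measurements, m)
  }
  if (!length(measurements))
    stop(npcError("npcIOError", "no cell could be quantified"))
  outCsv <- outCsv %||% file.path(dir, "cells.csv")
  writeCellCsv(measurements, outCsv)
  list(measurements = measurements,
       summary = summarizeGroup(measurements, label = basename(dir)),
       failures = failures)
}

#' Quantify a time-lapse TIFF
#'
#' Reads an interleaved (donor, acceptor, chromosome) multipage TIFF
#' written by `runSimulate("timelapse", ...)`, runs
#' [quantifyTimelapse()] and writes the per-frame CSV and half-time
#' JSON.
#'
#' @param path TIFF path.
#' @param frameInterval min between frames.
#' @param onsetFrame manual onset override (`NULL` to detect).
#' @param outCsv,outJson output paths (`NULL` for defaults next to the
#'   input).
#' @return The [TimelapseTrace-class].
#' @export
runQuantifyTimelapse <- function(path, frameInterval = 2,
                                 onsetFrame = NULL, outCsv = NULL,
                                 outJson = NULL) {
  pages <- readImageStack(path)
  if (length(pages) %% 3L != 0L)
    stop(npcError("npcIOError",
                  "expected an interleaved 3-channel stack"))
  nf <- length(pages) / 3L
  toStack <- function(off) {
    arr <- array(0, c(dim(pages[[1]]), nf))
    for (i in seq_len(nf)) arr[, , i] <- pages[[3L * (i - 1L) + off]]
    arr
  }
  trace <- quantifyTimelapse(toStack(1L), toStack(2L), toStack(3L),
                             frameInterval = frameInterval,
                             onsetFrame = onsetFrame)
  stem <- sub("\\.tif+$", "", path)
  writeTraceCsv(trace, outCsv %||% paste0(stem, "_trace.csv"),
                outJson %||% paste0(stem, "_halftimes.json"))
  trace
}

#' Fit a calibration from a spectrum batch manifest
#'
#' Reads the manifest CSV (see [readSpectrumManifest()]), computes the
#' A/D ratio of every spectrum, fits the quench calibration and writes it
#' to JSON.  A monotonicity warning is emitted when the fit is flagged.
#'
#' @param manifestPath manifest CSV path.
#' @param outJson output JSON path (`NULL` for
#'   `calibration.json` next to the manifest).
#' @param bands a [BandDefinition-class].
#' @return The fitted [CalibrationCurve-class].
#' @export
runCalibrate <- function(manifestPath, outJson = NULL,
                         bands = BandDefinition()) {
  mf <- readSpectrumManifest(manifestPath)
  pairs <- data.frame(
    concentration = mf$concentration_mg_per_ml,
    ratio = vapply(mf$spectrum, adRatio, numeric(1), bands = bands))
  curve <- fitCalibration(pairs)
  if (curve@nonMonotoneFlag)
    warning("calibration fit flagged non-monotone", call. = FALSE)
  writeCalibrationJson(curve, outJson %||%
                         file.path(dirname(manifestPath),
                                   "calibration.json"))
  curve
}
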