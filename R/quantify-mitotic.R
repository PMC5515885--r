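## Time-resolved localization / crowding quantification on mitotic stacks.

.chromThreshold <- function(frame) {
  rng <- range(frame)
  if (rng[2] <= rng[1]) return(matrix(FALSE, nrow(frame), ncol(frame)))
  norm <- (frame - rng[1]) / (rng[2] - rng[1])
  th <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  norm > th
}

.componentCentroids <- function(mask) {
  lab <- as.matrix(EBImage::bwlabel(EBImage::Image(mask * 1)))
  nlab <- max(lab)
  if (nlab < 1) return(NULL)
  sizes <- tabulate(lab[lab > 0], nbins = nlab)
  keep <- which(sizes >= 25)                 # ignore specks
  if (!length(keep)) return(NULL)
  cent <- t(vapply(keep, function(l) {
    idx <- which(lab == l, arr.ind = TRUE)
    c(mean(idx[, 1]), mean(idx[, 2]), sizes[l])
  }, numeric(3)))
  colnames(cent) <- c("x", "y", "size")
  cent
}

#' Detect anaphase onset from the chromosome-marker channel
#'
#' Anaphase onset is the first frame at which the thresholded chromosome
#' mask splits into at least two connected components whose centroids are
#' farther apart than `minDistance`, with the split persisting for at
#' least `persistence` consecutive frames (a one-frame spurious split is
#' ignored).
#'
#' @param chromosomeStack 3-d array (x, y, frame) of the marker channel.
#' @param minDistance minimum centroid separation in px (default 10).
#' @param persistence number of consecutive split frames required.
#' @return 1-based frame index of anaphase onset.
#' @export
detectAnaphaseOnset <- function(chromosomeStack, minDistance = 10,
                                persistence = 2L) {
  stopifnot(length(dim(chromosomeStack)) == 3L)
  nFrames <- dim(chromosomeStack)[3]
  split <- logical(nFrames)
  for (i in seq_len(nFrames)) {
    cent <- .componentCentroids(.chromThreshold(chromosomeStack[, , i]))
    if (is.null(cent) || nrow(cent) < 2L) next
    ord <- order(cent[, "size"], decreasing = TRUE)
    a <- cent[ord[1], ]; b <- cent[ord[2], ]
    split[i] <- sqrt((a["x"] - b["x"])^2 + (a["y"] - b["y"])^2) >
      minDistance
  }
  runlen <- 0L
  for (i in seq_len(nFrames)) {
    runlen <- if (split[i]) runlen + 1L else 0L
    if (runlen >= persistence)
      return(i - persistence + 1L)
  }
  stop(npcError("npcOnsetError",
                "no persistent chromosome separation found"))
}

#' Chromosome mask and surface-rim band of one frame
#'
#' Thresholds the chromosome-marker frame and returns the mask together
#' with a boundary band of width `rimWidth` just outside the union of the
#' chromosome components (both masses are banded after separation).
#'
#' @param chromosomeFrame numeric matrix (marker channel).
#' @param rimWidth band width in px.
#' @return List with logical matrices `chromosome` and `rim`.
#' @export
chromosomeRimMask <- function(chromosomeFrame, rimWidth = 3) {
  mask <- .chromThreshold(chromosomeFrame)
  if (!any(mask))
    stop(npcError("npcRegionError", "empty chromosome mask"))
  list(chromosome = mask, rim = .rimBand(mask, rimWidth))
}

#' Relative nuclear localization signal
#'
#' Donor excess on the chromosome rim over the cytoplasm:
#' `RNL = (rim mean - background) / (cytoplasm mean - background) - 1`,
#' clipped at 0.  The RNL is an affine-rescaled accumulation measure; the
#' half-time extraction downstream is insensitive to such rescaling.
#'
#' @param donorFrame numeric matrix.
#' @param rimMask,cytoMask logical matrices.
#' @param background donor background (counts).
#' @return Non-negative scalar.
#' @export
localizationSignal <- function(donorFrame, rimMask, cytoMask,
                               background = 0) {
  if (!any(rimMask) || !any(cytoMask))
    stop(npcError("npcRegionError", "empty rim or cytoplasm mask"))
  cyto <- mean(donorFrame[cytoMask]) - background
  if (cyto <= 0)
    stop(npcError("npcUndefinedRatioError",
                  "cytoplasm mean at or below background"))
  max((mean(donorFrame[rimMask]) - background) / cyto - 1, 0)
}

## Otsu threshold of a value vector (the histogram is all otsu needs).
.otsuValues <- function(v) {
  rng <- range(v)
  if (rng[2] <= rng[1]) return(rng[1])
  norm <- (v - rng[1]) / (rng[2] - rng[1])
  th <- EBImage::otsu(EBImage::Image(matrix(norm, nrow = 1)),
                      range = c(0, 1))
  th * (rng[2] - rng[1]) + rng[1]
}

## Cytoplasm reference region and camera background for a time-lapse
## frame: pixels well away from the chromosome masses split into
## bright (cytoplasm) and dim (extracellular background) classes by an
## Otsu threshold computed on that chromosome-free shell only, so the
## very bright rim band cannot skew the split.
.timelapseCytoBackground <- function(frame, chromMask, rimWidth) {
  far <- .outsideDistance(chromMask) > rimWidth + 8
  th <- .otsuValues(frame[far])
  cyto <- far & frame > th
  bgMask <- far & frame <= th
  list(cyto = cyto, bgMask = bgMask)
}

.maskMedian <- function(frame, mask) {
  if (any(mask)) stats::median(frame[mask]) else min(frame)
}

#' Probe time course on the chromosome rim
#'
#' Per frame, the probe signal is the rim A/D divided by the cytoplasm
#' A/D (see [probeSignal()]); the series is then normalized to its value
#' at the anaphase-onset frame (time 0), so the onset value is exactly 1.
#'
#' @param donorStack,acceptorStack,chromosomeStack 3-d arrays.
#' @param onsetFrame 1-based anaphase-onset frame.
#' @param rimWidth rim band width (px).
#' @param background list with `donor` and `acceptor` backgrounds, or
#'   `NULL` to estimate per frame as the median of the below-threshold
#'   (extracellular) pixel class.
#' @return Numeric vector, one probe value per frame (NA where the rim is
#'   empty).
#' @export
probeTimecourse <- function(donorStack, acceptorStack, chromosomeStack,
                            onsetFrame, rimWidth = 3, background = NULL) {
  nFrames <- dim(donorStack)[3]
  raw <- rep(NA_real_, nFrames)
  for (i in seq_len(nFrames)) {
    mk <- tryCatch(chromosomeRimMask(chromosomeStack[, , i], rimWidth),
                   error = function(e) NULL)
    if (is.null(mk)) next
    sp <- .timelapseCytoBackground(donorStack[, , i], mk$chromosome,
                                   rimWidth)
    bgD <- if (is.null(background))
      .maskMedian(donorStack[, , i], sp$bgMask) else background$donor
    bgA <- if (is.null(background))
      .maskMedian(acceptorStack[, , i], sp$bgMask)
    else background$acceptor
    rimAD <- probeSignal(acceptorStack[, , i], donorStack[, , i],
                         mk$rim, bgA, bgD)
    cytoAD <- probeSignal(acceptorStack[, , i], donorStack[, , i],
                          sp$cyto, bgA, bgD)
    raw[i] <- rimAD / cytoAD
  }
  if (is.na(raw[onsetFrame]) || raw[onsetFrame] <= 0)
    stop(npcError("npcUndefinedRatioError",
                  "probe signal undefined at the onset frame"))
  raw / raw[onsetFrame]
}

#' Extract the half-maximum / half-minimum crossing time
#'
#' The target level is the midpoint `(max + min)/2` of the series over
#' the window `times >= 0`.  The extreme on the target side (the maximum
#' of a rising trace, the minimum of a falling one) is taken from a
#' centred 3-frame moving average, which equals the plateau for
#' saturating traces and resists noise spikes, while still capturing the
#' peak of classes that decay after telophase; the extreme on the onset
#' side is taken from the raw series (it is exact by construction: the
#' probe series is 1 at time 0 and localization starts at 0).  The
#' earliest crossing in the requested direction is located by linear
#' interpolation between adjacent frames of the raw series.  A series
#' that never crosses the level is returned flagged unrecoverable rather
#' than an error, mirroring traces whose probe signal does not change
#' significantly.
#'
#' @param series numeric vector (>= 3 frames within the window).
#' @param times numeric vector of frame times (min after onset).
#' @param direction "rise" (localization) or "fall" (probe).
#' @return A [HalfTimeResult-class].
#' @examples
#' t <- seq(0, 30, 2)
#' extractHalfTime(kineticTrace(t, 1, log(2) / 3), t, "rise")  # ~4 min
#' @export
extractHalfTime <- function(series, times,
                            direction = c("rise", "fall")) {
  direction <- match.arg(direction)
  stopifnot(length(series) == length(times))
  win <- times >= 0 & !is.na(series)
  s <- series[win]; tt <- times[win]
  if (length(s) < 3L)
    stop(npcError("npcStatsError",
                  "need at least 3 post-onset frames"))
  nn <- length(s)
  sm <- vapply(seq_len(nn), function(i)
    mean(s[max(1L, i - 1L):min(nn, i + 1L)]), numeric(1))
  level <- if (direction == "rise")
    (max(sm) + min(s)) / 2
  else
    (min(sm) + max(s)) / 2

  unrec <- function() new("HalfTimeResult", time = NA_real_,
                          direction = direction, level = level,
                          recoverable = FALSE)
  if (max(s) == min(s)) return(unrec())

  for (i in seq_len(length(s) - 1L)) {
    crosses <- if (direction == "rise")
      s[i] < level && s[i + 1L] >= level
    else
      s[i] > level && s[i + 1L] <= level
    if (crosses) {
      frac <- (level - s[i]) / (s[i + 1L] - s[i])
      return(new("HalfTimeResult",
                 time = tt[i] + frac * (tt[i + 1L] - tt[i]),
                 direction = direction, level = level,
                 recoverable = TRUE))
    }
  }
  ## level already crossed at the first window frame
  first <- if (direction == "rise") s[1] >= level else s[1] <= level
  if (first)
    return(new("HalfTimeResult", time = tt[1], direction = direction,
               level = level, recoverable = TRUE))
  unrec()
}

#' Chromosome area time course
#'
#' Thresholded chromosome mask area per frame, normalized to the onset
#' frame.  Frames with no chromosome signal yield `NA` (a flagged gap,
#' not an error).
#'
#' @param chromosomeStack 3-d array.
#' @param onsetFrame 1-based onset frame index.
#' @return Numeric vector of relative areas.
#' @export
chromosomeAreaTimecourse <- function(chromosomeStack, onsetFrame = 1L) {
  nFrames <- dim(chromosomeStack)[3]
  area <- vapply(seq_len(nFrames), function(i) {
    m <- .chromThreshold(chromosomeStack[, , i])
    if (!any(m)) NA_real_ else sum(m)
  }, numeric(1))
  if (is.na(area[onsetFrame]) || area[onsetFrame] == 0)
    stop(npcError("npcRegionError",
                  "no chromosome signal at the onset frame"))
  area / area[onsetFrame]
}

#' Quantify a mitotic time-lapse stack
#'
#' Full trace extraction: detects anaphase onset (unless supplied),
#' computes the localization and probe series on the chromosome rim and
#' the relative chromosome area, and extracts the localization half-max
#' and probe half-min times.
#'
#' @param donorStack,acceptorStack,chromosomeStack 3-d arrays
#'   (x, y, frame).
#' @param frameInterval min between frames.
#' @param onsetFrame manual onset override (1-based); `NULL` to detect.
#' @param rimWidth rim band width (px).
#' @param background list with `donor` and `acceptor` background counts,
#'   or `NULL` to estimate per frame.
#' @return A [TimelapseTrace-class] with half-times filled in.
#' @examples
#' tl <- simulateTimelapse(timelapsePhantomConfig("early_assembler",
#'                                                noise = "none",
#'                                                imageSize = 96L))
#' tr <- quantifyTimelapse(tl$donor, tl$acceptor, tl$chromosome)
#' tr@halfTimes$localization
#' @export
quantifyTimelapse <- function(donorStack, acceptorStack, chromosomeStack,
                              frameInterval = 2, onsetFrame = NULL,
                              rimWidth = 3, background = NULL) {
  nFrames <- dim(donorStack)[3]
  if (is.null(onsetFrame))
    onsetFrame <- detectAnaphaseOnset(chromosomeStack)
  onsetFrame <- as.integer(onsetFrame)
  times <- (seq_len(nFrames) - onsetFrame) * frameInterval

  qc <- character()
  loc <- rep(NA_real_, nFrames)
  for (i in seq_len(nFrames)) {
    mk <- tryCatch(chromosomeRimMask(chromosomeStack[, , i], rimWidth),
                   error = function(e) NULL)
    if (is.null(mk)) { qc <- c(qc, sprintf("no-chromosome:frame%d", i)); next }
    sp <- .timelapseCytoBackground(donorStack[, , i], mk$chromosome,
                                   rimWidth)
    bgD <- if (is.null(background))
      .maskMedian(donorStack[, , i], sp$bgMask) else background$donor
    loc[i] <- localizationSignal(donorStack[, , i], mk$rim, sp$cyto, bgD)
  }
  probe <- probeTimecourse(donorStack, acceptorStack, chromosomeStack,
                           onsetFrame, rimWidth, background)
  area <- chromosomeAreaTimecourse(chromosomeStack, onsetFrame)

  locHalf <- tryCatch(extractHalfTime(loc, times, "rise"),
                      error = function(e) NULL)
  probeHalf <- tryCatch(extractHalfTime(probe, times, "fall"),
                        error = function(e) NULL)
  ht <- list()
  if (!is.null(locHalf)) ht$localization <- locHalf
  if (!is.null(probeHalf)) ht$probe <- probeHalf

  new("TimelapseTrace", times = times,
      localization = ifelse(is.na(loc), 0, loc),
      probe = probe, area = area, onsetFrame = onsetFrame,
      halfTimes = ht, qcFlags = qc)
}
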