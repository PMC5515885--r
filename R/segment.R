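## Nuclear-envelope rim segmentation from the donor channel.
##
## The donor (CFP) channel is used because it is crowding-insensitive:
## rim contrast in the acceptor channel is attenuated where crowding is
## high, which would bias a threshold.

.largestComponent <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  labm <- as.matrix(lab)
  if (max(labm) < 1) return(NULL)
  counts <- tabulate(labm[labm > 0])
  labm == which.max(counts)
}

#' Segment a single-cell donor image into regions
#'
#' Global Otsu thresholding of the (lightly smoothed) donor channel yields
#' the bright cell body; the nucleus is recovered as the largest enclosed
#' dim region (hole) of that body after hole-filling, and the
#' nuclear-envelope rim as a morphological band of width `rimWidth` just
#' outside the nucleus boundary.  Cytoplasm is the remaining cell body,
#' eroded away from the outer cell edge so PSF blur tails do not enter the
#' cytoplasm statistic; background is the complement.  Deterministic for
#' fixed input.  When several bodies are present the largest connected
#' component is taken.
#'
#' @param donor numeric matrix, donor-channel image (counts).
#' @param rimWidth rim band width in px (default 3).
#' @param smoothSigma Gaussian pre-smoothing sigma in px.
#' @param minNucleusPx smallest admissible nucleus size; below it
#'   segmentation fails with an `npcSegmentationError`.
#' @param maxRimOffset largest outward shift (px) considered when
#'   centring the rim band on the donor ridge.
#' @return A [RegionMasks-class].
#' @examples
#' ph <- simulateInterphaseCell(cellPhantomConfig("peripheral"))
#' masks <- segmentCell(ph$donor)
#' @export
segmentCell <- function(donor, rimWidth = 3, smoothSigma = 2,
                        minNucleusPx = 200, maxRimOffset = 8) {
  stopifnot(is.matrix(donor))
  rng <- range(donor)
  if (rng[2] <= rng[1])
    stop(npcError("npcSegmentationError",
                  "flat image: no cell found"))
  norm <- (donor - rng[1]) / (rng[2] - rng[1])
  sm <- .blur(norm, smoothSigma)
  th <- EBImage::otsu(EBImage::Image(sm), range = c(0, 1))
  fg <- sm > th

  body <- .largestComponent(fg)
  if (is.null(body) || sum(body) < 4 * minNucleusPx)
    stop(npcError("npcSegmentationError",
                  "no cell body found above the Otsu threshold"))
  if (mean(donor[fg]) < 1.2 * mean(donor[!fg]))
    stop(npcError("npcSegmentationError",
                  "insufficient foreground/background contrast"))
  filled <- as.matrix(EBImage::fillHull(EBImage::Image(body * 1))) > 0.5

  holes <- filled & !body
  nucleus <- .largestComponent(holes)
  if (is.null(nucleus) || sum(nucleus) < minNucleusPx)
    stop(npcError("npcSegmentationError", sprintf(
      "no nucleus found (largest enclosed dim region %d px < %d px)",
      if (is.null(nucleus)) 0L else sum(nucleus), minNucleusPx)))
  nucleus <- as.matrix(
    EBImage::fillHull(EBImage::Image(nucleus * 1))) > 0.5

  ## PSF blur erodes the thresholded hole inward of the true nuclear
  ## boundary; recover it by sliding the candidate rim band outward and
  ## keeping the offset whose band is brightest in the donor channel
  ## (the NE ridge).
  dn <- .outsideDistance(nucleus)
  offsets <- seq(0, maxRimOffset, by = 1)
  score <- vapply(offsets, function(o) {
    band <- dn > o & dn <= o + rimWidth
    if (!any(band)) -Inf else mean(donor[band])
  }, numeric(1))
  off <- offsets[which.max(score)]
  nucleus <- nucleus | dn <= off
  rim <- dn > off & dn <= off + rimWidth

  ## keep the cytoplasm mask clear of the blurred outer cell edge
  interior <- as.matrix(EBImage::erode(
    EBImage::Image(filled * 1),
    EBImage::makeBrush(9, shape = "disc"))) > 0.5

  labels <- matrix(0L, nrow(donor), ncol(donor))
  labels[interior & !nucleus & !rim] <- 1L
  labels[nucleus] <- 2L
  labels[rim] <- 3L

  new("RegionMasks", labels = labels, rimWidth = rimWidth)
}

#' Estimate the per-channel background level
#'
#' Median of the background-mask pixels at least `clearance` px away
#' from any non-background label, so PSF blur tails at the cell edge do
#' not bias the estimate.
#'
#' @param image numeric matrix.
#' @param masks a [RegionMasks-class].
#' @param clearance minimum distance (px) from the cell.
#' @return Scalar background estimate (counts).
#' @export
estimateBackground <- function(image, masks, clearance = 8) {
  labels <- regionLabels(masks)
  far <- labels == 0L & .outsideDistance(labels > 0L) > clearance
  if (!any(far)) far <- labels == 0L
  if (!any(far))
    stop(npcError("npcSegmentationError", "empty background mask"))
  stats::median(image[far])
}
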