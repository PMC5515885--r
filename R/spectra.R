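## Band statistics on emission spectra and the acceptor quench model.

npcError <- function(class, message, ...) {
  structure(class = c(class, "npcrowdError", "error", "condition"),
            list(message = message, call = sys.call(-1), ...))
}

#' Band-integrated fluorescence intensity
#'
#' Sums the intensities at all grid points lambda with
#' `lo <= lambda <= hi`, both endpoints inclusive.  The statistic is an
#' inclusive grid-point sum, not a quadrature: the measured "total value" of
#' the fluorescence over a band.  Its absolute value therefore depends on
#' the grid step; only ratios of band sums taken on the same grid are
#' interpreted downstream.
#'
#' @param spectrum an [EmissionSpectrum-class].
#' @param lo,hi band limits in nm.
#' @return Sum of intensities over the band (a.u.).
#' @examples
#' sp <- EmissionSpectrum(450:600, rep(1, 151))
#' integrateBand(sp, 460, 500)  # 41 grid points
#' @export
integrateBand <- function(spectrum, lo, hi) {
  stopifnot(is(spectrum, "EmissionSpectrum"))
  if (lo >= hi)
    stop(npcError("npcBandError", "band requires lo < hi"))
  wl <- spectrum@wavelength
  step <- wl[2] - wl[1]
  eps <- 1e-9 * step
  sel <- wl >= lo - eps & wl <= hi + eps
  if (!any(sel))
    stop(npcError("npcBandError", sprintf(
      "band [%g, %g] nm contains no grid point (grid %g-%g nm)",
      lo, hi, min(wl), max(wl))))
  sum(spectrum@intensity[sel])
}

#' Acceptor/donor (A/D) ratio of a spectrum
#'
#' The probe signal: band-integrated acceptor fluorescence (520--570 nm by
#' default) divided by band-integrated donor fluorescence (460--500 nm).
#' Lower A/D indicates higher macromolecular crowding.  The ratio is exactly
#' invariant under positive rescaling of the intensities.
#'
#' @param spectrum an [EmissionSpectrum-class].
#' @param bands a [BandDefinition-class].
#' @param epsilon smallest admissible donor band sum; below it the ratio is
#'   undefined and an error of class `npcUndefinedRatioError` is signalled.
#' @return Dimensionless A/D ratio.
#' @examples
#' sp <- EmissionSpectrum(450:600, rep(1, 151))
#' adRatio(sp)  # 51/41
#' @export
adRatio <- function(spectrum, bands = BandDefinition(), epsilon = 1e-12) {
  stopifnot(is(bands, "BandDefinition"))
  don <- integrateBand(spectrum, bands@donor[1], bands@donor[2])
  acc <- integrateBand(spectrum, bands@acceptor[1], bands@acceptor[2])
  if (don <= epsilon)
    stop(npcError("npcUndefinedRatioError", sprintf(
      "donor band sum %g is at or below epsilon = %g; A/D undefined",
      don, epsilon)))
  acc / don
}

#' Crowding-dependent acceptor quench factor
#'
#' The fraction of acceptor (YFP1G) fluorescence remaining at crowder
#' concentration `C` (mg/mL): `f(C) = max(1 - slope * C, floor)`.  The
#' model is linear with a saturation floor; the default slope 1/500 per
#' (mg/mL) and floor 0.2 give a usable dynamic range beyond 200 mg/mL.
#' The donor (CFP) is crowding-insensitive and is never scaled.
#'
#' @param C crowder concentration in mg/mL (vectorized, must be `>= 0`).
#' @param slope quench slope per (mg/mL).
#' @param floor minimum quench factor, in (0, 1].
#' @return Quench factor(s) in `(0, 1]`.
#' @examples
#' quenchFactor(c(0, 100, 200, 600))
#' @export
quenchFactor <- function(C, slope = 1 / 500, floor = 0.2) {
  if (any(C < 0))
    stop(npcError("npcDomainError",
                  "concentration must be non-negative"))
  stopifnot(floor > 0, floor <= 1, slope >= 0)
  pmax(1 - slope * C, floor)
}
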