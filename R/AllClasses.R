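#' @import methods
NULL

## ---------------------------------------------------------------------------
## Spectra
## ---------------------------------------------------------------------------

#' EmissionSpectrum: a fluorescence emission spectrum on a uniform grid
#'
#' Wavelength-indexed fluorescence intensities recorded under a single
#' excitation wavelength (433 nm for the CFP/YFP1G pair).  The wavelength
#' grid must be strictly increasing and uniform; intensities are arbitrary
#' fluorescence units and must be non-negative.  Absolute scale carries no
#' meaning downstream -- only band-integrated ratios are interpreted.
#'
#' @slot wavelength numeric, wavelengths in nm (strictly increasing, uniform
#'   step).
#' @slot intensity numeric, fluorescence intensities (a.u., `>= 0`), same
#'   length as `wavelength`.
#' @slot excitation numeric(1), excitation wavelength in nm.
#' @slot label character(1), free-text label (probe, crowder, concentration).
#' @exportClass EmissionSpectrum
setClass("EmissionSpectrum",
  representation(
    wavelength = "numeric",
    intensity  = "numeric",
    excitation = "numeric",
    label      = "character"
  ),
  prototype(excitation = 433, label = "")
)

setValidity("EmissionSpectrum", function(object) {
  wl <- object@wavelength
  it <- object@intensity
  msg <- character()
  if (length(wl) < 2L)
    msg <- c(msg, "need at least two wavelength samples")
  if (length(wl) != length(it))
    msg <- c(msg, "wavelength and intensity lengths differ")
  if (anyNA(wl) || anyNA(it))
    msg <- c(msg, "NA values are not allowed")
  if (length(wl) >= 2L) {
    d <- diff(wl)
    if (any(d <= 0))
      msg <- c(msg, "wavelength grid must be strictly increasing")
    else if (max(d) - min(d) > 1e-9 * mean(d))
      msg <- c(msg, "wavelength grid must be uniform (constant step)")
  }
  if (length(it) && min(it) < 0)
    msg <- c(msg, "intensities must be non-negative")
  if (length(object@excitation) != 1L || object@excitation <= 0)
    msg <- c(msg, "excitation must be a single positive wavelength")
  if (length(msg)) msg else TRUE
})

#' Construct an EmissionSpectrum
#'
#' @param wavelength numeric vector of wavelengths (nm), strictly increasing
#'   on a uniform grid.
#' @param intensity numeric vector of non-negative intensities (a.u.).
#' @param excitation excitation wavelength in nm (default 433).
#' @param label free-text label.
#' @return An [EmissionSpectrum-class] object.
#' @examples
#' sp <- EmissionSpectrum(450:600, rep(1, 151))
#' adRatio(sp)
#' @export
EmissionSpectrum <- function(wavelength, intensity, excitation = 433,
                             label = "") {
  new("EmissionSpectrum",
      wavelength = as.numeric(wavelength),
      intensity  = as.numeric(intensity),
      excitation = as.numeric(excitation),
      label      = as.character(label))
}

#' BandDefinition: donor and acceptor integration bands
#'
#' Wavelength windows over which donor and acceptor fluorescence are
#' band-integrated.  Defaults follow the CFP/YFP1G imaging convention:
#' donor 460--500 nm, acceptor 520--570 nm, both endpoints inclusive on the
#' sample grid.
#'
#' @slot donor numeric(2), donor band (lo, hi) in nm.
#' @slot acceptor numeric(2), acceptor band (lo, hi) in nm.
#' @exportClass BandDefinition
setClass("BandDefinition",
  representation(donor = "numeric", acceptor = "numeric"),
  prototype(donor = c(460, 500), acceptor = c(520, 570))
)

setValidity("BandDefinition", function(object) {
  d <- object@donor; a <- object@acceptor
  msg <- character()
  if (length(d) != 2L || length(a) != 2L)
    msg <- c(msg, "bands must be length-2 (lo, hi)")
  else {
    if (d[1] >= d[2]) msg <- c(msg, "donor band needs lo < hi")
    if (a[1] >= a[2]) msg <- c(msg, "acceptor band needs lo < hi")
    if (max(d[1], a[1]) <= min(d[2], a[2]))
      msg <- c(msg, "donor and acceptor bands must not overlap")
  }
  if (length(msg)) msg else TRUE
})

#' @param donor numeric(2) donor band in nm.
#' @param acceptor numeric(2) acceptor band in nm.
#' @return A [BandDefinition-class] object.
#' @rdname BandDefinition-class
#' @export
BandDefinition <- function(donor = c(460, 500), acceptor = c(520, 570)) {
  new("BandDefinition", donor = as.numeric(donor),
      acceptor = as.numeric(acceptor))
}

#' CalibrationCurve: fitted concentration-to-A/D map
#'
#' The linear-with-floor quench calibration
#' \eqn{A/D(C) = r_0 \cdot \max(1 - s\,C, \phi)}, where \eqn{r_0} is the
#' A/D ratio at zero crowder concentration, \eqn{s} the quench slope per
#' (mg/mL) and \eqn{\phi} the minimum quench factor (saturation floor).
#' The predicted ratio is non-increasing in concentration by construction.
#'
#' @slot ratioAtZero numeric(1), A/D at C = 0 (instrument dependent, > 0).
#' @slot slope numeric(1), quench slope per (mg/mL), `>= 0`.
#' @slot floor numeric(1), minimum quench factor in (0, 1].
#' @slot fittedOn data.frame with columns `concentration`, `ratio`.
#' @slot residualRms numeric(1), root-mean-square fit residual.
#' @slot nonMonotoneFlag logical(1), TRUE when the input pairs were
#'   incompatible with a non-increasing calibration.
#' @exportClass CalibrationCurve
setClass("CalibrationCurve",
  representation(
    ratioAtZero     = "numeric",
    slope           = "numeric",
    floor           = "numeric",
    fittedOn        = "data.frame",
    residualRms     = "numeric",
    nonMonotoneFlag = "logical"
  ),
  prototype(fittedOn = data.frame(concentration = numeric(),
                                  ratio = numeric()),
            residualRms = NA_real_, nonMonotoneFlag = FALSE)
)

setValidity("CalibrationCurve", function(object) {
  msg <- character()
  if (length(object@ratioAtZero) != 1L || object@ratioAtZero <= 0)
    msg <- c(msg, "ratioAtZero must be a single positive value")
  if (length(object@slope) != 1L || object@slope < 0)
    msg <- c(msg, "slope must be a single non-negative value")
  if (length(object@floor) != 1L || object@floor <= 0 || object@floor > 1)
    msg <- c(msg, "floor must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Phantom configuration and ground truth
## ---------------------------------------------------------------------------

#' CellPhantomConfig: interphase cell phantom parameters
#'
#' Geometry, optics and biochemistry of a synthetic interphase cell: a
#' bright cytoplasmic disk, a dim nucleus, and a bright nuclear-envelope rim
#' band carrying the NPC-embedded probe.  Concentrations are crowder
#' concentrations (mg/mL) entering the acceptor quench model; densities are
#' relative probe expression levels scaling both channels equally.
#'
#' @slot imageSize integer(1), square frame side in pixels.
#' @slot cellRadius numeric(1), cytoplasm disk radius (px).
#' @slot nucleusRadiusRange numeric(2), min/max nucleus radius (px) sampled
#'   per cell.
#' @slot rimWidth numeric(1), nuclear-envelope band width (px, `>= 1`).
#' @slot concCyto,concRim,concNucleus numeric(1), crowder concentration
#'   (mg/mL) in each region.
#' @slot densityCyto,densityRim,densityNucleus numeric(1), relative probe
#'   density per region.
#' @slot psfSigma numeric(1), Gaussian PSF sigma (px).
#' @slot background numeric(1), camera background offset (counts).
#' @slot photonScale numeric(1), counts per density unit.
#' @slot baselineAD numeric(1), unquenched acceptor/donor ratio.
#' @slot noise character(1), "poisson" or "none".
#' @slot seed integer(1), RNG seed for geometry jitter and shot noise.
#' @slot preset character(1), name of the preset this config came from.
#' @exportClass CellPhantomConfig
setClass("CellPhantomConfig",
  representation(
    imageSize          = "integer",
    cellRadius         = "numeric",
    nucleusRadiusRange = "numeric",
    rimWidth           = "numeric",
    concCyto           = "numeric",
    concRim            = "numeric",
    concNucleus        = "numeric",
    densityCyto        = "numeric",
    densityRim         = "numeric",
    densityNucleus     = "numeric",
    psfSigma           = "numeric",
    background         = "numeric",
    photonScale        = "numeric",
    baselineAD         = "numeric",
    noise              = "character",
    seed               = "integer",
    preset             = "character"
  )
)

setValidity("CellPhantomConfig", function(object) {
  msg <- character()
  if (object@imageSize < 32L)
    msg <- c(msg, "imageSize must be at least 32 px")
  if (object@rimWidth < 1)
    msg <- c(msg, "rimWidth must be >= 1 px")
  if (any(c(object@concCyto, object@concRim, object@concNucleus) < 0))
    msg <- c(msg, "concentrations must be non-negative")
  if (any(c(object@densityCyto, object@densityRim,
            object@densityNucleus) < 0))
    msg <- c(msg, "densities must be non-negative")
  if (!object@noise %in% c("poisson", "none"))
    msg <- c(msg, "noise must be 'poisson' or 'none'")
  rmax <- max(object@nucleusRadiusRange) + object@rimWidth
  if (rmax >= object@cellRadius)
    msg <- c(msg, "nucleus plus rim must fit inside the cell radius")
  if (2 * object@cellRadius >= object@imageSize)
    msg <- c(msg, "cell must fit inside the frame")
  if (length(msg)) msg else TRUE
})

#' TimelapsePhantomConfig: mitotic time-lapse phantom parameters
#'
#' Parameters of a synthetic anaphase-to-G1 sequence: two elliptical
#' chromosome masses separating after anaphase onset, a chromosome-rim band
#' accumulating probe with first-order kinetics
#' \eqn{L(t) = 1 - e^{-k (t - t_0)}} (0 before \eqn{t_0}), and a rim crowder
#' concentration ramping from `concStart` to `concPlateau` in proportion to
#' the (undecayed) localization curve.  Early-assembling classes may decay
#' after telophase (`telophaseDecay` > 0) without affecting the
#' concentration ramp, reproducing the dissociation signature in which
#' localization falls while crowding persists.
#'
#' @slot imageSize integer(1), square frame side (px).
#' @slot cellRadius numeric(1), radius of the cytoplasm disk (px); pixels
#'   outside it are camera background.
#' @slot frameInterval numeric(1), min between frames (default 2).
#' @slot duration numeric(1), min covered after anaphase onset.
#' @slot onsetFrame integer(1), 1-based frame index at which chromosome
#'   masses first separate.
#' @slot separationVelocity numeric(1), px/frame separation speed.
#' @slot t0 numeric(1), localization onset, min after anaphase onset.
#' @slot k numeric(1), localization rate (1/min, > 0).
#' @slot plateauDensity numeric(1), rim probe density at plateau.
#' @slot telophaseDecay numeric(1), post-telophase decay rate (1/min, 0 for
#'   none).
#' @slot telophaseStart numeric(1), min after onset at which decay begins.
#' @slot concStart,concPlateau numeric(1), rim crowder concentration ramp
#'   endpoints (mg/mL).
#' @slot concCyto numeric(1), cytoplasm crowder concentration (mg/mL).
#' @slot densityCyto,densityChrom numeric(1), probe density in cytoplasm and
#'   inside chromosome masses.
#' @slot chromMarkerDensity numeric(1), chromosome-marker channel density.
#' @slot decondensationGrowth numeric(1), relative chromosome area at the
#'   last frame (1 = static; 1.5 = linear growth to 1.5x), emulating
#'   telophase decondensation.
#' @slot rimWidth numeric(1), chromosome-rim band width (px).
#' @slot psfSigma,background,photonScale,baselineAD,noise,seed,preset as in
#'   [CellPhantomConfig-class].
#' @exportClass TimelapsePhantomConfig
setClass("TimelapsePhantomConfig",
  representation(
    imageSize          = "integer",
    cellRadius         = "numeric",
    frameInterval      = "numeric",
    duration           = "numeric",
    onsetFrame         = "integer",
    separationVelocity = "numeric",
    t0                 = "numeric",
    k                  = "numeric",
    plateauDensity     = "numeric",
    telophaseDecay     = "numeric",
    telophaseStart     = "numeric",
    concStart          = "numeric",
    concPlateau        = "numeric",
    concCyto           = "numeric",
    densityCyto        = "numeric",
    densityChrom       = "numeric",
    chromMarkerDensity = "numeric",
    decondensationGrowth = "numeric",
    rimWidth           = "numeric",
    psfSigma           = "numeric",
    background         = "numeric",
    photonScale        = "numeric",
    baselineAD         = "numeric",
    noise              = "character",
    seed               = "integer",
    preset             = "character"
  )
)

setValidity("TimelapsePhantomConfig", function(object) {
  msg <- character()
  if (object@frameInterval <= 0) msg <- c(msg, "frameInterval must be > 0")
  if (object@t0 < 0) msg <- c(msg, "t0 must be >= 0")
  if (object@k <= 0) msg <- c(msg, "k must be > 0")
  if (object@telophaseDecay < 0)
    msg <- c(msg, "telophaseDecay must be >= 0")
  if (object@onsetFrame < 1L) msg <- c(msg, "onsetFrame must be >= 1")
  if (!object@noise %in% c("poisson", "none"))
    msg <- c(msg, "noise must be 'poisson' or 'none'")
  if (any(c(object@concStart, object@concPlateau, object@concCyto) < 0))
    msg <- c(msg, "concentrations must be non-negative")
  if (length(msg)) msg else TRUE
})

#' PhantomManifest: ground truth emitted with every synthetic dataset
#'
#' Carries the exact region label masks (0 = background, 1 = cytoplasm,
#' 2 = nucleus/chromosome interior, 3 = rim), the crowder concentration map,
#' the generating configuration, and the analytically expected read-outs
#' (relative probe signal, half-times) so that pipeline output can be scored
#' against construction-time truth.
#'
#' @slot labels matrix (interphase) or list of matrices (time-lapse), region
#'   label images.
#' @slot concMap matrix or list of matrices, crowder concentration (mg/mL)
#'   per pixel.
#' @slot expected list of analytically expected quantities (e.g.
#'   `relativeProbe`, `halfMaxTime`, `plateauProbeDrop`).
#' @slot config the generating configuration object.
#' @slot kind character(1), one of "interphase", "immunostain",
#'   "timelapse".
#' @exportClass PhantomManifest
setClass("PhantomManifest",
  representation(
    labels   = "ANY",
    concMap  = "ANY",
    expected = "list",
    config   = "ANY",
    kind     = "character"
  )
)

setValidity("PhantomManifest", function(object) {
  if (!object@kind %in% c("interphase", "immunostain", "timelapse"))
    "kind must be 'interphase', 'immunostain' or 'timelapse'"
  else TRUE
})

## ---------------------------------------------------------------------------
## Quantification results
## ---------------------------------------------------------------------------

#' RegionMasks: segmentation of a single-cell frame
#'
#' Integer label image partitioning the frame into background (0),
#' cytoplasm (1), nucleus (2) and nuclear-envelope rim (3), plus the rim
#' width used.  Labels are mutually exclusive by construction.
#'
#' @slot labels integer matrix of region labels.
#' @slot rimWidth numeric(1), rim band width (px).
#' @exportClass RegionMasks
setClass("RegionMasks",
  representation(labels = "matrix", rimWidth = "numeric"))

setValidity("RegionMasks", function(object) {
  lv <- unique(as.vector(object@labels))
  if (!all(lv %in% 0:3))
    return("labels must be integers in 0..3")
  TRUE
})

#' CellMeasurement: per-cell ratiometric read-out
#'
#' Background-subtracted region statistics for one cell: the probe signal
#' (A/D) at the nuclear envelope and in the cytoplasm, their ratio
#' (`relativeProbe`, the per-cell crowding statistic), and donor rim/cyto
#' intensities used in the expression-independence control.
#'
#' @slot cellId character(1).
#' @slot probeNE numeric(1), A/D over the rim mask.
#' @slot probeCyto numeric(1), A/D over the cytoplasm mask.
#' @slot relativeProbe numeric(1), `probeNE / probeCyto`.
#' @slot localizationNE numeric(1), background-subtracted donor rim mean.
#' @slot localizationCyto numeric(1), background-subtracted donor cytoplasm
#'   mean.
#' @slot qcFlags character vector of QC annotations (empty when clean).
#' @exportClass CellMeasurement
setClass("CellMeasurement",
  representation(
    cellId           = "character",
    probeNE          = "numeric",
    probeCyto        = "numeric",
    relativeProbe    = "numeric",
    localizationNE   = "numeric",
    localizationCyto = "numeric",
    qcFlags          = "character"
  ),
  prototype(qcFlags = character())
)

setValidity("CellMeasurement", function(object) {
  if (!is.na(object@relativeProbe) && object@relativeProbe <= 0)
    "relativeProbe must be positive"
  else TRUE
})

#' GroupSummary: descriptive statistics for a group of cells
#'
#' Mean and SD (n-1 denominator), median, quartiles (linear-interpolation
#' convention) and 1.5*IQR outliers, matching the boxplot presentation used
#' for treatment comparisons.
#'
#' @slot label character(1), group label.
#' @slot n integer(1), number of cells.
#' @slot mean,sd,median,q1,q3 numeric(1) summary statistics (`sd` is `NA`
#'   for n = 1).
#' @slot outliers numeric, values beyond 1.5*IQR from the quartiles.
#' @exportClass GroupSummary
setClass("GroupSummary",
  representation(
    label    = "character",
    n        = "integer",
    mean     = "numeric",
    sd       = "numeric",
    median   = "numeric",
    q1       = "numeric",
    q3       = "numeric",
    outliers = "numeric"
  )
)

setValidity("GroupSummary", function(object) {
  msg <- character()
  if (object@n < 1L) msg <- c(msg, "n must be >= 1")
  if (!anyNA(c(object@q1, object@median, object@q3)) &&
      !(object@q1 <= object@median && object@median <= object@q3))
    msg <- c(msg, "need q1 <= median <= q3")
  if (length(msg)) msg else TRUE
})

#' TreatmentComparison: reference-vs-treated group comparison
#'
#' Treated probe signals normalized to the reference group mean (the
#' "relative value to intact cells" convention), with a two-tailed Welch
#' t-test on the unnormalized values.
#'
#' @slot referenceLabel,treatedLabel character(1).
#' @slot relativeValues numeric, treated values / reference mean.
#' @slot relativeMean numeric(1).
#' @slot tStatistic,df,pValue numeric(1), Welch test results.
#' @slot referenceSummary,treatedSummary [GroupSummary-class] objects.
#' @exportClass TreatmentComparison
setClass("TreatmentComparison",
  representation(
    referenceLabel   = "character",
    treatedLabel     = "character",
    relativeValues   = "numeric",
    relativeMean     = "numeric",
    tStatistic       = "numeric",
    df               = "numeric",
    pValue           = "numeric",
    referenceSummary = "GroupSummary",
    treatedSummary   = "GroupSummary"
  )
)

setValidity("TreatmentComparison", function(object) {
  msg <- character()
  if (!is.na(object@pValue) &&
      (object@pValue < 0 || object@pValue > 1))
    msg <- c(msg, "pValue must lie in [0, 1]")
  if (!is.na(object@df) && object@df <= 0)
    msg <- c(msg, "df must be positive")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Time-lapse traces
## ---------------------------------------------------------------------------

#' TimelapseTrace: per-frame localization and probe series
#'
#' Localization signal (relative nuclear localization of the donor on the
#' chromosome rim), probe signal (rim/cyto A/D, normalized to its value at
#' anaphase onset) and chromosome area per frame, on a time axis in minutes
#' after anaphase onset (negative before onset).
#'
#' @slot times numeric, min after anaphase onset, strictly increasing with
#'   constant step.
#' @slot localization numeric, relative nuclear localization per frame
#'   (`>= 0`).
#' @slot probe numeric, probe signal relative to the onset frame (> 0; may
#'   be NA on QC-flagged frames).
#' @slot area numeric, chromosome mask area relative to the onset frame.
#' @slot onsetFrame integer(1), 1-based index of the anaphase-onset frame.
#' @slot halfTimes list of [HalfTimeResult-class] (filled by
#'   [quantifyTimelapse()]).
#' @slot qcFlags character vector.
#' @exportClass TimelapseTrace
setClass("TimelapseTrace",
  representation(
    times        = "numeric",
    localization = "numeric",
    probe        = "numeric",
    area         = "numeric",
    onsetFrame   = "integer",
    halfTimes    = "list",
    qcFlags      = "character"
  ),
  prototype(halfTimes = list(), qcFlags = character())
)

setValidity("TimelapseTrace", function(object) {
  msg <- character()
  tt <- object@times
  if (length(tt) >= 2L) {
    d <- diff(tt)
    if (any(d <= 0))
      msg <- c(msg, "times must be strictly increasing")
    else if (max(d) - min(d) > 1e-6 * mean(d))
      msg <- c(msg, "times must have a constant frame interval")
  }
  if (length(object@localization) &&
      any(object@localization < 0, na.rm = TRUE))
    msg <- c(msg, "localization must be >= 0")
  if (length(object@probe) && any(object@probe <= 0, na.rm = TRUE))
    msg <- c(msg, "probe values must be positive")
  if (length(msg)) msg else TRUE
})

#' HalfTimeResult: half-maximum / half-minimum crossing time
#'
#' The earliest time a rising (localization) or falling (probe) trace
#' crosses the midpoint between its extremes over the post-onset window,
#' obtained by linear interpolation between adjacent frames.  When the
#' trace never crosses the midpoint the result is flagged unrecoverable
#' (`time` is `NA`), mirroring traces whose probe signal does not change
#' significantly.
#'
#' @slot time numeric(1), crossing time in min after anaphase onset (`NA`
#'   when unrecoverable).
#' @slot direction character(1), "rise" or "fall".
#' @slot level numeric(1), the half level used.
#' @slot recoverable logical(1).
#' @slot method character(1), convention identifier recorded in outputs.
#' @exportClass HalfTimeResult
setClass("HalfTimeResult",
  representation(
    time        = "numeric",
    direction   = "character",
    level       = "numeric",
    recoverable = "logical",
    method      = "character"
  ),
  prototype(method = "midpoint-linear-interpolation/plateau-last3")
)

setValidity("HalfTimeResult", function(object) {
  if (!object@direction %in% c("rise", "fall"))
    "direction must be 'rise' or 'fall'"
  else TRUE
})
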