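## Named phantom presets.  Concentrations are chosen so that, routed
## through the default quench model f(C) = max(1 - C/500, 0.2), they
## reproduce the characteristic probe-signal reductions of each NPC
## region class; they are generator conventions, not measured values.

.interphasePresets <- list(
  ## nucleoplasmic/cytoplasmic peripheral FG-Nups: ~25% reduction
  peripheral     = list(concRim = 200, concCyto = 100, concNucleus = 100),
  ## central cavity (Nup54/58/62-like): ~10% reduction
  central_cavity = list(concRim = 140, concCyto = 100, concNucleus = 100),
  ## scaffold subunits: large but sub-peripheral reduction (~20%)
  scaffold       = list(concRim = 180, concCyto = 100, concNucleus = 100)
)

.immunostainPresets <- list(
  ## digitonin-permeabilized importin-beta immunostain: the soluble
  ## cytoplasmic pool is washed out, signal is rim-localized
  digitonin_immunostain = list(retention = 0.70, densityCyto = 0.1,
                               densityNucleus = 0.1, densityRim = 3)
)

.kineticPresets <- list(
  ## scaffold / nucleoplasmic early assembler (Nup160-like): t0 = 1 min,
  ## decays after telophase while crowding persists
  early_assembler = list(t0 = 1, k = log(2) / 3, telophaseDecay = 0.04,
                         telophaseStart = 10, concStart = 100,
                         concPlateau = 180),
  ## membrane-spanning subunit (Pom121-like): t0 = 3 min
  pom121_like     = list(t0 = 3, k = log(2) / 3, telophaseDecay = 0,
                         telophaseStart = Inf, concStart = 100,
                         concPlateau = 180),
  ## cytoplasmic-domain late assembler (Nup214-like): t0 = 10 min
  late_assembler  = list(t0 = 10, k = log(2) / 3, telophaseDecay = 0,
                         telophaseStart = Inf, concStart = 100,
                         concPlateau = 180)
)

#' List available phantom presets
#'
#' @return Named list with `interphase`, `immunostain` and `kinetic`
#'   preset names.
#' @export
phantomPresets <- function() {
  list(interphase = names(.interphasePresets),
       immunostain = names(.immunostainPresets),
       kinetic = names(.kineticPresets))
}

#' Build an interphase cell phantom configuration
#'
#' Resolves a named preset (see [phantomPresets()]) into a full
#' [CellPhantomConfig-class]; any explicitly supplied argument overrides
#' the preset value.
#'
#' @param preset preset name or `NULL` for the raw defaults.
#' @param imageSize frame side in px.
#' @param cellRadius,nucleusRadiusRange,rimWidth geometry in px.
#' @param concCyto,concRim,concNucleus crowder concentrations (mg/mL).
#' @param densityCyto,densityRim,densityNucleus relative probe densities.
#' @param psfSigma,background,photonScale,baselineAD optics.
#' @param noise "poisson" or "none".
#' @param seed RNG seed.
#' @return A validated [CellPhantomConfig-class].
#' @examples
#' cellPhantomConfig("peripheral", seed = 1)
#' @export
cellPhantomConfig <- function(preset = NULL,
                              imageSize = 256L,
                              cellRadius = 110,
                              nucleusRadiusRange = c(55, 70),
                              rimWidth = 3,
                              concCyto = 100,
                              concRim = 200,
                              concNucleus = 100,
                              densityCyto = 1,
                              densityRim = 3,
                              densityNucleus = 0.15,
                              psfSigma = 1.5,
                              background = 100,
                              photonScale = 200,
                              baselineAD = 1.2,
                              noise = c("poisson", "none"),
                              seed = 1L) {
  noise <- match.arg(noise)
  given <- names(match.call())[-1]
  if (!is.null(preset)) {
    p <- .interphasePresets[[preset]]
    if (is.null(p))
      stop(npcError("npcConfigError",
                    sprintf("unknown interphase preset '%s'", preset)))
    for (nm in names(p))
      if (!nm %in% given) assign(nm, p[[nm]])
  }
  new("CellPhantomConfig",
      imageSize = as.integer(imageSize), cellRadius = cellRadius,
      nucleusRadiusRange = nucleusRadiusRange, rimWidth = rimWidth,
      concCyto = concCyto, concRim = concRim, concNucleus = concNucleus,
      densityCyto = densityCyto, densityRim = densityRim,
      densityNucleus = densityNucleus, psfSigma = psfSigma,
      background = background, photonScale = photonScale,
      baselineAD = baselineAD, noise = noise, seed = as.integer(seed),
      preset = if (is.null(preset)) "custom" else preset)
}

#' Build a mitotic time-lapse phantom configuration
#'
#' Resolves a kinetic preset (see [phantomPresets()]) into a full
#' [TimelapsePhantomConfig-class]; explicit arguments override preset
#' values.  Frames are captured every `frameInterval` minutes; the stack
#' starts `onsetFrame - 1` frames before anaphase onset and covers
#' `duration` minutes after it.
#'
#' @param preset kinetic preset name or `NULL`.
#' @param imageSize frame side in px.
#' @param cellRadius cytoplasm disk radius in px (background outside).
#' @param frameInterval min between frames.
#' @param duration min after anaphase onset.
#' @param onsetFrame 1-based frame at which the chromosome masses separate.
#' @param separationVelocity px/frame.
#' @param t0,k localization kinetics: onset (min after anaphase onset) and
#'   rate (1/min).
#' @param plateauDensity rim probe density at plateau.
#' @param telophaseDecay,telophaseStart optional post-telophase decay of
#'   the localization density (rate 1/min; start in min after onset).
#' @param concStart,concPlateau,concCyto crowder concentrations (mg/mL).
#' @param densityCyto,densityChrom,chromMarkerDensity probe / marker
#'   densities.
#' @param decondensationGrowth relative chromosome area at the last frame
#'   (1 = static).
#' @param rimWidth,psfSigma,background,photonScale,baselineAD optics.
#' @param noise "poisson" or "none".
#' @param seed RNG seed.
#' @return A validated [TimelapsePhantomConfig-class].
#' @examples
#' timelapsePhantomConfig("early_assembler", seed = 1)
#' @export
timelapsePhantomConfig <- function(preset = NULL,
                                   imageSize = 256L,
                                   cellRadius = 115,
                                   frameInterval = 2,
                                   duration = 30,
                                   onsetFrame = 4L,
                                   separationVelocity = 2,
                                   t0 = 1,
                                   k = log(2) / 3,
                                   plateauDensity = 3,
                                   telophaseDecay = 0,
                                   telophaseStart = Inf,
                                   concStart = 100,
                                   concPlateau = 180,
                                   concCyto = 100,
                                   densityCyto = 1,
                                   densityChrom = 0.2,
                                   chromMarkerDensity = 3,
                                   decondensationGrowth = 1,
                                   rimWidth = 3,
                                   psfSigma = 1.5,
                                   background = 100,
                                   photonScale = 200,
                                   baselineAD = 1.2,
                                   noise = c("poisson", "none"),
                                   seed = 1L) {
  noise <- match.arg(noise)
  given <- names(match.call())[-1]
  if (!is.null(preset)) {
    p <- .kineticPresets[[preset]]
    if (is.null(p))
      stop(npcError("npcConfigError",
                    sprintf("unknown kinetic preset '%s'", preset)))
    for (nm in names(p))
      if (!nm %in% given) assign(nm, p[[nm]])
  }
  new("TimelapsePhantomConfig",
      imageSize = as.integer(imageSize), cellRadius = cellRadius,
      frameInterval = frameInterval,
      duration = duration, onsetFrame = as.integer(onsetFrame),
      separationVelocity = separationVelocity, t0 = t0, k = k,
      plateauDensity = plateauDensity, telophaseDecay = telophaseDecay,
      telophaseStart = telophaseStart, concStart = concStart,
      concPlateau = concPlateau, concCyto = concCyto,
      densityCyto = densityCyto, densityChrom = densityChrom,
      chromMarkerDensity = chromMarkerDensity,
      decondensationGrowth = decondensationGrowth, rimWidth = rimWidth,
      psfSigma = psfSigma, background = background,
      photonScale = photonScale, baselineAD = baselineAD, noise = noise,
      seed = as.integer(seed),
      preset = if (is.null(preset)) "custom" else preset)
}
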