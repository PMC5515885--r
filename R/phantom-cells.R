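## Interphase cell and immunostain phantoms.
##
## Image formation model (per channel, per pixel x):
##   donor(x)    = background + photonScale * Dblur(x)
##   acceptor(x) = background + photonScale * Dblur(x) * baselineAD * f(C(x))
## where Dblur is the probe density field convolved with a Gaussian PSF and
## f is the acceptor quench factor evaluated on the *unblurred* crowder
## concentration map (crowding is a pixelwise property of the local
## concentration, not an optical one).  Optional per-pixel Poisson noise is
## applied independently per channel.

.distFrom <- function(size, cx, cy) {
  x <- matrix(seq_len(size), size, size)
  y <- matrix(seq_len(size), size, size, byrow = TRUE)
  sqrt((x - cx)^2 + (y - cy)^2)
}

.blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  as.matrix(EBImage::gblur(EBImage::Image(m), sigma = sigma))
}

.poissonize <- function(m) {
  matrix(stats::rpois(length(m), lambda = pmax(m, 0)),
         nrow(m), ncol(m))
}

## Build label/density/concentration fields for one interphase cell.
.interphaseFields <- function(config) {
  n <- config@imageSize
  rN <- stats::runif(1, config@nucleusRadiusRange[1],
                     config@nucleusRadiusRange[2])
  maxOff <- max(config@cellRadius - rN - config@rimWidth - 12, 0)
  off <- stats::runif(2, -1, 1) * min(10, maxOff)
  ctr <- (n + 1) / 2
  dCell <- .distFrom(n, ctr, ctr)
  dNuc <- .distFrom(n, ctr + off[1], ctr + off[2])

  labels <- matrix(0L, n, n)
  labels[dCell <= config@cellRadius] <- 1L                  # cytoplasm
  labels[dNuc <= rN + config@rimWidth] <- 3L                # rim band
  labels[dNuc <= rN] <- 2L                                  # nucleus

  density <- matrix(0, n, n)
  density[labels == 1L] <- config@densityCyto
  density[labels == 2L] <- config@densityNucleus
  density[labels == 3L] <- config@densityRim

  conc <- matrix(0, n, n)
  conc[labels == 1L] <- config@concCyto
  conc[labels == 2L] <- config@concNucleus
  conc[labels == 3L] <- config@concRim

  list(labels = labels, density = density, conc = conc)
}

#' Simulate a two-channel interphase cell image
#'
#' Generates a donor/acceptor image pair of a single interphase cell with
#' a bright nuclear-envelope rim and diffuse cytoplasmic probe, plus a
#' [PhantomManifest-class] carrying the exact region masks, the
#' concentration map, and the analytically expected read-outs.  The
#' expected relative probe signal is the quench-factor ratio
#' `f(concRim) / f(concCyto)` and does not depend on probe density --
#' expression level and crowding are decoupled by construction.
#'
#' @param config a [CellPhantomConfig-class] (see [cellPhantomConfig()]).
#' @return List with elements `donor`, `acceptor` (count matrices) and
#'   `manifest` ([PhantomManifest-class]).
#' @examples
#' ph <- simulateInterphaseCell(cellPhantomConfig("peripheral",
#'                                                noise = "none"))
#' expectedValues(ph$manifest)$relativeProbe  # 0.75
#' @export
simulateInterphaseCell <- function(config = cellPhantomConfig()) {
  stopifnot(is(config, "CellPhantomConfig"))
  validObject(config)
  withLocalSeed(config@seed, {
    fld <- .interphaseFields(config)
    dens <- .blur(fld$density, config@psfSigma)
    f <- quenchFactor(fld$conc)
    donor <- config@background + config@photonScale * dens
    acceptor <- config@background +
      config@photonScale * dens * config@baselineAD * f
    if (config@noise == "poisson") {
      donor <- .poissonize(donor)
      acceptor <- .poissonize(acceptor)
    }
    fRim <- quenchFactor(config@concRim)
    fCyto <- quenchFactor(config@concCyto)
    expected <- list(
      relativeProbe = fRim / fCyto,
      probeNE = config@baselineAD * fRim,
      probeCyto = config@baselineAD * fCyto,
      background = config@background)
    manifest <- new("PhantomManifest", labels = fld$labels,
                    concMap = fld$conc, expected = expected,
                    config = config, kind = "interphase")
    .checkManifestConsistency(manifest)
    list(donor = donor, acceptor = acceptor, manifest = manifest)
  })
}

## Expected values must be re-derivable from the stored concentration map;
## verified at generation time.
.checkManifestConsistency <- function(manifest) {
  if (manifest@kind != "interphase") return(invisible(TRUE))
  lab <- manifest@labels
  conc <- manifest@concMap
  fr <- mean(quenchFactor(conc[lab == 3L]))
  fc <- mean(quenchFactor(conc[lab == 1L]))
  if (abs(fr / fc - manifest@expected$relativeProbe) > 1e-9)
    stop(npcError("npcManifestError",
                  "manifest expected values inconsistent with maps"))
  invisible(TRUE)
}

#' Simulate an intact/treated immunostain image pair
#'
#' Single-channel images emulating an NPC immunostain before and after a
#' treatment that removes a fraction of the rim-bound protein: the treated
#' rim density is `retention` times the intact one, with identical
#' geometry and optics (same seed).  The default configuration mimics a
#' digitonin-permeabilized cell: the soluble cytoplasmic pool is washed
#' out, so the signal is rim-localized.
#'
#' @param retention fraction of rim density retained after treatment, in
#'   `[0, 1]` (0.70 for the digitonin importin-beta control).
#' @param config a [CellPhantomConfig-class]; default uses washed-out
#'   cytoplasm/nucleus densities (0.1).
#' @return List with `intact`, `treated` (count matrices) and `manifest`.
#' @examples
#' pr <- simulateImmunostainPair(0.70)
#' expectedValues(pr$manifest)$retention
#' @export
simulateImmunostainPair <- function(retention = 0.70, config = NULL) {
  if (is.null(config))
    config <- cellPhantomConfig(densityCyto = 0.1, densityNucleus = 0.1,
                                densityRim = 3)
  stopifnot(is(config, "CellPhantomConfig"))
  if (retention < 0 || retention > 1)
    stop(npcError("npcConfigError", "retention must lie in [0, 1]"))
  withLocalSeed(config@seed, {
    fld <- .interphaseFields(config)
    densTreated <- fld$density
    densTreated[fld$labels == 3L] <- config@densityRim * retention
    intact <- config@background +
      config@photonScale * .blur(fld$density, config@psfSigma)
    treated <- config@background +
      config@photonScale * .blur(densTreated, config@psfSigma)
    if (config@noise == "poisson") {
      intact <- .poissonize(intact)
      treated <- .poissonize(treated)
    }
    manifest <- new("PhantomManifest", labels = fld$labels,
                    concMap = fld$conc,
                    expected = list(retention = retention,
                                    background = config@background),
                    config = config, kind = "immunostain")
    list(intact = intact, treated = treated, manifest = manifest)
  })
}
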