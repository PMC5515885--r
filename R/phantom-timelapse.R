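## Anaphase-to-G1 time-lapse phantoms.
##
## Two elliptical chromosome masses overlap before anaphase onset and
## separate at a constant velocity after it.  A rim band on the chromosome
## surface accumulates probe density with first-order kinetics
## L(t) = 1 - exp(-k (t - t0)) for t >= t0 (0 before), optionally decaying
## after telophase for early-assembling classes.  The rim crowder
## concentration ramps from concStart to concPlateau in proportion to the
## *undecayed* localization curve, so crowding persists when early
## assemblers dissociate.

#' First-order localization kinetics
#'
#' Evaluates the rim localization curve
#' \eqn{L(t) = 1 - e^{-k (t - t_0)}} for `t >= t0` (0 before), optionally
#' multiplied by \eqn{e^{-k_d (t - t_{telo})}} after `telophaseStart`.
#' The analytic half-maximum time of the undecayed curve is
#' `t0 + log(2)/k`.
#'
#' @param times numeric vector, min after anaphase onset.
#' @param t0 localization onset (min).
#' @param k rate (1/min, > 0).
#' @param telophaseDecay decay rate after telophase (1/min; 0 disables).
#' @param telophaseStart decay start (min after onset).
#' @return Numeric vector of localization fractions in `[0, 1]`.
#' @examples
#' kineticTrace(seq(0, 30, 2), t0 = 1, k = log(2) / 3)
#' @export
kineticTrace <- function(times, t0, k, telophaseDecay = 0,
                         telophaseStart = Inf) {
  stopifnot(k > 0, t0 >= 0)
  L <- ifelse(times < t0, 0, 1 - exp(-k * (times - t0)))
  if (telophaseDecay > 0) {
    dec <- ifelse(times > telophaseStart,
                  exp(-telophaseDecay * (times - telophaseStart)), 1)
    L <- L * dec
  }
  L
}

## Union of the two elliptical chromosome masses at a given separation.
.chromMask <- function(size, separation, rx = 20, ry = 34,
                       areaScale = 1) {
  ctr <- (size + 1) / 2
  x <- matrix(seq_len(size), size, size)
  y <- matrix(seq_len(size), size, size, byrow = TRUE)
  s <- sqrt(areaScale)
  inEllipse <- function(cx) {
    ((x - cx) / (rx * s))^2 + ((y - ctr) / (ry * s))^2 <= 1
  }
  inEllipse(ctr - separation / 2) | inEllipse(ctr + separation / 2)
}

## Euclidean distance (px) from each outside pixel to the mask; 0 inside.
.outsideDistance <- function(mask) {
  as.matrix(EBImage::distmap(EBImage::Image((!mask) * 1)))
}

## Boundary band of width rimWidth outside the mask, optionally offset
## outward; the single band convention used for NE and chromosome rims.
.rimBand <- function(mask, rimWidth, offset = 0) {
  d <- .outsideDistance(mask)
  d > offset & d <= offset + rimWidth
}

#' Simulate a mitotic three-channel time-lapse stack
#'
#' Generates donor, acceptor and chromosome-marker channel stacks for a
#' post-mitotic NPC reassembly phantom, plus a manifest with per-frame
#' ground-truth label masks, rim concentrations, the analytic half-maximum
#' time `t0 + log(2)/k` and the expected plateau probe drop
#' `1 - f(concPlateau)/f(concStart)`.
#'
#' Frames are `frameInterval` minutes apart; frame `onsetFrame` is
#' anaphase onset (time 0).  Before onset the two chromosome masses
#' overlap; at onset they become disjoint and then separate at
#' `separationVelocity` px/frame.
#'
#' @param config a [TimelapsePhantomConfig-class]
#'   (see [timelapsePhantomConfig()]).
#' @return List with `donor`, `acceptor`, `chromosome` (arrays, frame as
#'   third dimension), `times` (min after onset) and `manifest`.
#' @examples
#' tl <- simulateTimelapse(timelapsePhantomConfig("early_assembler",
#'                                                noise = "none",
#'                                                imageSize = 96L))
#' expectedValues(tl$manifest)$halfMaxTime  # 4 min
#' @export
simulateTimelapse <- function(config = timelapsePhantomConfig()) {
  stopifnot(is(config, "TimelapsePhantomConfig"))
  validObject(config)
  n <- config@imageSize
  nFrames <- config@onsetFrame +
    as.integer(round(config@duration / config@frameInterval))
  times <- (seq_len(nFrames) - config@onsetFrame) * config@frameInterval
  post <- times >= 0

  rx <- min(20, n / 8); ry <- min(34, n / 4.5)
  baseSep <- 2 * rx + 6

  Lloc <- kineticTrace(times, config@t0, config@k,
                       config@telophaseDecay, config@telophaseStart)
  Lramp <- kineticTrace(times, config@t0, config@k)
  rimConc <- config@concStart +
    (config@concPlateau - config@concStart) * Lramp
  rimConc[!post] <- config@concStart

  growth <- if (config@decondensationGrowth != 1 && any(post)) {
    g <- rep(1, nFrames)
    idx <- which(post)
    g[idx] <- seq(1, config@decondensationGrowth, length.out = length(idx))
    g
  } else rep(1, nFrames)

  ctr <- (n + 1) / 2
  cell <- .distFrom(n, ctr, ctr) <= min(config@cellRadius, n / 2 - 6)

  withLocalSeed(config@seed, {
    donor <- acceptor <- chrom <- array(0, c(n, n, nFrames))
    labels <- vector("list", nFrames)
    for (i in seq_len(nFrames)) {
      sep <- if (i < config@onsetFrame) rx else
        baseSep + config@separationVelocity * (i - config@onsetFrame)
      mask <- .chromMask(n, sep, rx, ry, growth[i])
      rim <- .rimBand(mask, config@rimWidth)

      lab <- matrix(0L, n, n)
      lab[cell] <- 1L               # cytoplasm inside the cell disk
      lab[rim] <- 3L
      lab[mask] <- 2L
      labels[[i]] <- lab

      density <- matrix(0, n, n)
      density[cell] <- config@densityCyto
      density[rim] <- config@densityCyto +
        config@plateauDensity * Lloc[i]
      density[mask] <- config@densityChrom

      conc <- matrix(0, n, n)
      conc[cell | rim] <- config@concCyto
      conc[rim] <- rimConc[i]

      dens <- .blur(density, config@psfSigma)
      donor[, , i] <- config@background + config@photonScale * dens
      acceptor[, , i] <- config@background + config@photonScale * dens *
        config@baselineAD * quenchFactor(conc)
      marker <- matrix(0, n, n)
      marker[mask] <- config@chromMarkerDensity
      chrom[, , i] <- config@background +
        config@photonScale * .blur(marker, config@psfSigma)
    }
    if (config@noise == "poisson") {
      donor <- array(stats::rpois(length(donor), donor), dim(donor))
      acceptor <- array(stats::rpois(length(acceptor), acceptor),
                        dim(acceptor))
      chrom <- array(stats::rpois(length(chrom), chrom), dim(chrom))
    }

    halfMax <- config@t0 + log(2) / config@k
    fS <- quenchFactor(config@concStart)
    fP <- quenchFactor(config@concPlateau)
    expected <- list(
      times = times,
      localization = Lloc,
      rimConcentration = rimConc,
      probeSeries = quenchFactor(rimConc) / fS,
      plateauProbeDrop = 1 - fP / fS,
      halfMaxTime = halfMax,
      halfMaxRecoverable = halfMax <= config@duration,
      onsetFrame = config@onsetFrame,
      areaSeries = growth,
      background = config@background)
    manifest <- new("PhantomManifest", labels = labels,
                    concMap = rimConc, expected = expected,
                    config = config, kind = "timelapse")
    list(donor = donor, acceptor = acceptor, chromosome = chrom,
         times = times, manifest = manifest)
  })
}
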