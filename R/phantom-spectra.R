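## Synthetic GimRET / CFP-wtYFP emission spectra.

## Evaluate the RNG-consuming expression `expr` under `seed` without
## disturbing the caller's RNG state (full determinism contract).
withLocalSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Component shapes on the default 450-600 nm grid.  The donor (CFP-like)
## component is two Gaussians (475 and 501 nm); the acceptor (YFP1G-like)
## component is one Gaussian at 527 nm.  Components are truncated at a
## 510-nm crossover so each integration band sees a single fluorophore:
## an idealized, spectrally separated phantom (real CFP/YFP spectra
## overlap; only band ratios matter downstream).
.donorShape <- function(wl) {
  v <- exp(-(wl - 475)^2 / (2 * 15^2)) +
    0.45 * exp(-(wl - 501)^2 / (2 * 15^2))
  v[wl > 510] <- 0
  v
}

.acceptorShape <- function(wl, amplitude = 2.1) {
  v <- amplitude * exp(-(wl - 527)^2 / (2 * 12^2))
  v[wl <= 510] <- 0
  v
}

#' Baseline A/D ratio of the synthetic probe spectrum
#'
#' The A/D ratio of the noise-free synthetic GimRET spectrum at zero
#' crowder concentration (about 1.2 with the default shapes).
#'
#' @param bands a [BandDefinition-class].
#' @return Dimensionless baseline ratio.
#' @export
baselineSpectrumRatio <- function(bands = BandDefinition()) {
  adRatio(simulateSpectrum("GimRET", C = 0), bands)
}

#' Simulate an emission spectrum of a crowding probe
#'
#' Generates a synthetic emission spectrum for the crowding-sensitive
#' GimRET probe or the insensitive CFP-wtYFP control at crowder
#' concentration `C`.  The donor component is unchanged by `C`; the
#' acceptor component is scaled by [quenchFactor()] for GimRET and left
#' unscaled for CFP-wtYFP.  Optional additive Gaussian noise is clipped at
#' zero to respect the non-negativity invariant.
#'
#' @param probe "GimRET" or "CFP-wtYFP".
#' @param C crowder concentration (mg/mL, `>= 0`).
#' @param noiseSd additive Gaussian noise SD (a.u.; 0 for noise-free).
#' @param seed RNG seed (only used when `noiseSd > 0`).
#' @param wavelength wavelength grid in nm.
#' @param slope,floor quench model parameters.
#' @return An [EmissionSpectrum-class] labelled with probe and
#'   concentration.
#' @examples
#' s0 <- simulateSpectrum("GimRET", C = 0)
#' s1 <- simulateSpectrum("GimRET", C = 100)
#' adRatio(s1) / adRatio(s0)  # 0.8 under the default quench model
#' @export
simulateSpectrum <- function(probe = c("GimRET", "CFP-wtYFP"), C = 0,
                             noiseSd = 0, seed = NULL,
                             wavelength = 450:600,
                             slope = 1 / 500, floor = 0.2) {
  probe <- match.arg(probe)
  if (C < 0)
    stop(npcError("npcDomainError", "concentration must be non-negative"))
  f <- if (probe == "GimRET") quenchFactor(C, slope, floor) else 1
  int <- .donorShape(wavelength) + f * .acceptorShape(wavelength)
  if (noiseSd > 0) {
    int <- withLocalSeed(seed,
                         int + stats::rnorm(length(int), sd = noiseSd))
    int <- pmax(int, 0)
  }
  EmissionSpectrum(wavelength, int,
                   label = sprintf("%s C=%g mg/mL", probe, C))
}
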