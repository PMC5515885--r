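# Band statistics, A/D ratios and the quench model.

test_that("EmissionSpectrum enforces its grid and sign invariants", {
  expect_s4_class(EmissionSpectrum(450:600, rep(1, 151)),
                  "EmissionSpectrum")
  expect_error(EmissionSpectrum(c(450, 451, 453), c(1, 1, 1)),
               "uniform")
  expect_error(EmissionSpectrum(c(450, 450, 451), c(1, 1, 1)),
               "increasing")
  expect_error(EmissionSpectrum(450:452, c(1, -1, 1)), "non-negative")
  expect_error(EmissionSpectrum(450:452, c(1, 1)), "lengths")
})

test_that("integrateBand is an inclusive grid-point sum", {
  zero <- EmissionSpectrum(450:600, rep(0, 151))
  expect_identical(integrateBand(zero, 520, 570), 0)

  flat <- EmissionSpectrum(450:600, rep(1, 151))
  expect_equal(integrateBand(flat, 460, 500), 41)
  expect_equal(integrateBand(flat, 520, 570), 51)

  expect_error(integrateBand(flat, 700, 750), class = "npcBandError")
  expect_error(integrateBand(flat, 500, 460), class = "npcBandError")
})

test_that("integrateBand matches an independent numerical oracle", {
  wl <- 450:600
  f <- function(x) exp(-(x - 475)^2 / (2 * 15^2)) +
    0.8 * exp(-(x - 527)^2 / (2 * 12^2))
  sp <- EmissionSpectrum(wl, f(wl))

  for (band in list(c(460, 500), c(520, 570))) {
    # independent selection + summation oracle on the sampled values
    oracle <- sum(f(wl)[wl >= band[1] & wl <= band[2]])
    expect_equal(integrateBand(sp, band[1], band[2]), oracle,
                 tolerance = 1e-9)
    # grid-sum times step approximates a fine trapezoid quadrature of
    # the continuous shape (band-edge truncation limits the agreement)
    xf <- seq(band[1], band[2], by = 0.001)
    quad <- sum((f(xf)[-1] + f(xf)[-length(xf)]) / 2 * diff(xf))
    expect_equal(integrateBand(sp, band[1], band[2]) * 1, quad,
                 tolerance = 0.02)
  }
})

test_that("adRatio follows the band convention and is scale invariant", {
  flat <- EmissionSpectrum(450:600, rep(1, 151))
  expect_equal(adRatio(flat), 51 / 41)

  sp <- simulateSpectrum("GimRET", C = 3)
  scaled <- EmissionSpectrum(wavelength(sp), 7.3 * intensity(sp))
  expect_equal(adRatio(scaled), adRatio(sp), tolerance = 1e-14)

  donorless <- EmissionSpectrum(450:600,
                                ifelse(450:600 >= 520, 1, 0))
  expect_error(adRatio(donorless), class = "npcUndefinedRatioError")
})

test_that("A/D of the synthetic probe decreases monotonically with C", {
  conc <- c(0, 10, 50, 100, 200, 300, 390)
  ratios <- vapply(conc, function(C)
    adRatio(simulateSpectrum("GimRET", C)), numeric(1))
  expect_true(all(diff(ratios) < 0))
})

test_that("quenchFactor implements the linear-with-floor model", {
  expect_identical(quenchFactor(0), 1)
  expect_equal(quenchFactor(100), 0.8)
  expect_equal(quenchFactor(200), 0.6)
  expect_equal(quenchFactor(600), 0.2)   # floor clamp
  expect_equal(quenchFactor(1e6), 0.2)
  expect_error(quenchFactor(-1), class = "npcDomainError")
  # vectorized and non-increasing
  C <- seq(0, 700, by = 7)
  expect_true(all(diff(quenchFactor(C)) <= 0))
})
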