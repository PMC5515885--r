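# Fitting and inverting the concentration -> A/D calibration.

test_that("noiseless pairs are recovered to high precision", {
  C <- c(0, 2, 5, 10)
  pairs <- data.frame(concentration = C,
                      ratio = 1.23 * quenchFactor(C))
  curve <- fitCalibration(pairs)
  expect_equal(curve@slope, 1 / 500, tolerance = 1e-6)
  expect_equal(curve@ratioAtZero, 1.23, tolerance = 1e-6)
  expect_false(curve@nonMonotoneFlag)
  expect_lt(curve@residualRms, 1e-8)
})

test_that("fit + invert round-trips concentrations on the linear segment", {
  C <- c(0, 25, 60, 120, 250)
  curve <- fitCalibration(data.frame(concentration = C,
                                     ratio = 1.1 * quenchFactor(C)))
  for (c0 in c(0.5, 10, 100, 350)) {
    expect_equal(invertCalibration(predictRatio(curve, c0), curve), c0,
                 tolerance = 1e-6)
  }
})

test_that("noisy replicate fits recover the slope on average", {
  C <- c(0, 2, 5, 10, 50, 100, 200)
  r0 <- 1.2
  truth <- r0 * quenchFactor(C)
  slopes <- withr::with_seed(42, vapply(seq_len(200), function(i) {
    noisy <- truth + rnorm(length(C), sd = 0.01 * r0)
    fitCalibration(data.frame(concentration = C, ratio = noisy))@slope
  }, numeric(1)))
  expect_equal(mean(slopes), 1 / 500, tolerance = 0.05)
})

test_that("ratios increasing with concentration flag the fit", {
  pairs <- data.frame(concentration = c(0, 50, 100, 200),
                      ratio = c(1.0, 1.1, 1.2, 1.4))
  curve <- fitCalibration(pairs)
  expect_true(curve@nonMonotoneFlag)
  # monotonicity invariant still enforced on the fitted curve
  C <- seq(0, 600, by = 5)
  expect_true(all(diff(predictRatio(curve, C)) <= 0))
})

test_that("inversion saturates outside the invertible range", {
  C <- c(0, 50, 100, 200)
  curve <- fitCalibration(data.frame(concentration = C,
                                     ratio = 1.2 * quenchFactor(C)))
  expect_equal(invertCalibration(curve@ratioAtZero, curve), 0)
  expect_equal(invertCalibration(0.8 * curve@ratioAtZero, curve), 100,
               tolerance = 1e-6)

  errHigh <- tryCatch(invertCalibration(1.5 * curve@ratioAtZero, curve),
                      npcSaturationError = function(e) e)
  expect_s3_class(errHigh, "npcSaturationError")
  expect_equal(errHigh$boundary, 0)

  errLow <- tryCatch(invertCalibration(0.1 * curve@ratioAtZero, curve),
                     npcSaturationError = function(e) e)
  expect_s3_class(errLow, "npcSaturationError")
  expect_equal(errLow$boundary, (1 - curve@floor) / curve@slope,
               tolerance = 1e-6)
})

test_that("under-determined input is rejected", {
  expect_error(fitCalibration(data.frame(concentration = c(0, 10),
                                         ratio = c(1.2, 1.1))),
               class = "npcCalibrationError")
})
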