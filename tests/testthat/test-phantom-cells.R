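# Interphase cell and immunostain phantoms.

test_that("manifest expected values follow the quench-factor ratios", {
  periph <- simulateInterphaseCell(smallCellConfig("peripheral"))
  expect_equal(expectedValues(periph$manifest)$relativeProbe, 0.75)

  cavity <- simulateInterphaseCell(smallCellConfig("central_cavity"))
  expect_equal(expectedValues(cavity$manifest)$relativeProbe, 0.90)

  flat <- simulateInterphaseCell(smallCellConfig(concRim = 100,
                                                 concCyto = 100,
                                                 densityRim = 6))
  expect_equal(expectedValues(flat$manifest)$relativeProbe, 1.0)
})

test_that("label masks partition the frame into the four regions", {
  ph <- simulateInterphaseCell(smallCellConfig("peripheral"))
  lab <- regionLabels(manifestMasks(ph$manifest))
  expect_true(all(lab %in% 0:3))
  expect_true(all(vapply(0:3, function(l) sum(lab == l) > 0, logical(1))))
  expect_identical(length(lab), 160L * 160L)
})

test_that("generation is bit-identical for identical seed and config", {
  a <- simulateInterphaseCell(smallCellConfig("peripheral", seed = 5,
                                              noise = "poisson"))
  b <- simulateInterphaseCell(smallCellConfig("peripheral", seed = 5,
                                              noise = "poisson"))
  expect_identical(a$donor, b$donor)
  expect_identical(a$acceptor, b$acceptor)
  d <- simulateInterphaseCell(smallCellConfig("peripheral", seed = 6,
                                              noise = "poisson"))
  expect_false(identical(a$donor, d$donor))
})

test_that("probe density changes intensities but not expected crowding", {
  lo <- simulateInterphaseCell(smallCellConfig("peripheral"))
  hi <- simulateInterphaseCell(smallCellConfig("peripheral",
                                               densityRim = 6))
  rim <- regionLabels(manifestMasks(lo$manifest)) == 3L
  expect_gt(mean(hi$donor[rim]), mean(lo$donor[rim]))
  expect_identical(expectedValues(hi$manifest)$relativeProbe,
                   expectedValues(lo$manifest)$relativeProbe)
})

test_that("degenerate geometry is rejected at config validation", {
  expect_error(cellPhantomConfig(imageSize = 64L, cellRadius = 60),
               "fit inside the frame")
  expect_error(cellPhantomConfig(nucleusRadiusRange = c(100, 120)),
               "fit inside the cell")
  expect_error(cellPhantomConfig("no_such_preset"),
               class = "npcConfigError")
})

test_that("immunostain pair scales the rim by the retention factor", {
  cfg <- smallCellConfig(densityCyto = 0.1, densityNucleus = 0.1)
  same <- simulateImmunostainPair(1, cfg)
  expect_identical(same$intact, same$treated)

  gone <- simulateImmunostainPair(0, cfg)
  rim <- regionLabels(manifestMasks(gone$manifest)) == 3L
  # treated rim carries only background + blur bleed from neighbours
  expect_lt(mean(gone$treated[rim]) - 100, 0.12 * 200)
  # PSF spreads the 3-px band, so the band mean sits well below the
  # peak density but far above the washed-out surroundings
  expect_gt(mean(gone$intact[rim]) - 100, 0.55 * 3 * 200)

  part <- simulateImmunostainPair(0.7, cfg)
  ratio <- (mean(part$treated[rim]) - 100) / (mean(part$intact[rim]) - 100)
  expect_equal(ratio, 0.7, tolerance = 0.03)
  expect_error(simulateImmunostainPair(1.2, cfg),
               class = "npcConfigError")
})
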