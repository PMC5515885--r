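# Per-cell ratiometric quantification and group statistics.

test_that("probeSignal is a ratio of background-subtracted means", {
  donor <- matrix(10, 8, 8)
  acceptor <- 2 * donor
  mask <- matrix(TRUE, 8, 8)
  expect_equal(probeSignal(acceptor, donor, mask), 2)

  # exact invariance to a constant offset supplied as the background
  expect_equal(probeSignal(acceptor + 37, donor + 37, mask,
                           bgAcceptor = 37, bgDonor = 37), 2)

  expect_error(probeSignal(acceptor, donor, mask & FALSE),
               class = "npcRegionError")
  expect_error(probeSignal(acceptor, matrix(0, 8, 8), mask),
               class = "npcUndefinedRatioError")
})

test_that("noise-free pipeline matches the analytic quench ratio per preset", {
  for (preset in phantomPresets()$interphase) {
    ph <- simulateInterphaseCell(smallCellConfig(preset))
    truthMasks <- manifestMasks(ph$manifest)
    m <- measureCell(ph$donor, ph$acceptor, truthMasks,
                     background = trueBackground(ph$manifest))
    expect_equal(m@relativeProbe,
                 expectedValues(ph$manifest)$relativeProbe,
                 tolerance = 1e-6, label = preset)

    seg <- measureCell(ph$donor, ph$acceptor, segmentCell(ph$donor),
                       background = trueBackground(ph$manifest))
    expect_lt(abs(seg@relativeProbe -
                  expectedValues(ph$manifest)$relativeProbe), 0.015)
  }
})

test_that("relative probe is independent of probe expression level", {
  base <- simulateInterphaseCell(smallCellConfig("peripheral"))
  doubled <- simulateInterphaseCell(smallCellConfig("peripheral",
                                                    densityRim = 6,
                                                    densityCyto = 2,
                                                    densityNucleus = 0.3))
  bg <- trueBackground(base$manifest)
  m1 <- measureCell(base$donor, base$acceptor,
                    manifestMasks(base$manifest), background = bg)
  m2 <- measureCell(doubled$donor, doubled$acceptor,
                    manifestMasks(doubled$manifest), background = bg)
  expect_gt(m2@localizationNE, 1.5 * m1@localizationNE)
  expect_lt(abs(m2@probeNE - m1@probeNE), 0.01)
  expect_lt(abs(m2@relativeProbe - m1@relativeProbe), 0.01)
})

test_that("mean noisy recovery stays near the generating quench ratio", {
  rel <- vapply(1:20, function(s) {
    ph <- simulateInterphaseCell(cellPhantomConfig("peripheral",
                                                   seed = s))
    measureCell(ph$donor, ph$acceptor,
                segmentCell(ph$donor))@relativeProbe
  }, numeric(1))
  expect_gte(mean(rel), 0.73)
  expect_lte(mean(rel), 0.77)
})

test_that("QC flags small regions", {
  ph <- simulateInterphaseCell(smallCellConfig("peripheral"))
  m <- measureCell(ph$donor, ph$acceptor, manifestMasks(ph$manifest),
                   background = trueBackground(ph$manifest),
                   minRegionPx = 1e6)
  expect_true(any(grepl("small-region", m@qcFlags)))
})

test_that("summarizeGroup reproduces hand-computed statistics", {
  g <- summarizeGroup(c(1, 2, 3, 4, 5))
  expect_equal(g@mean, 3)
  expect_equal(g@sd, sqrt(2.5), tolerance = 1e-12)
  expect_equal(g@median, 3)
  expect_equal(g@q1, 2)
  expect_equal(g@q3, 4)
  expect_length(g@outliers, 0)

  single <- summarizeGroup(7)
  expect_true(is.na(single@sd))
  expect_equal(single@q1, 7)
  expect_equal(single@q3, 7)

  out <- summarizeGroup(c(1, 2, 3, 4, 5, 100))
  expect_equal(out@outliers, 100)
})

test_that("Welch test matches the direct formula and handles edge cases", {
  same <- welchTTest(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  ab <- welchTTest(1:5, 2:6)
  expect_equal(ab$t, -1, tolerance = 1e-12)
  expect_equal(ab$df, 8, tolerance = 1e-12)

  # direct Welch-Satterthwaite formula as the independent oracle
  directWelch <- function(a, b) {
    va <- var(a) / length(a); vb <- var(b) / length(b)
    t <- (mean(a) - mean(b)) / sqrt(va + vb)
    df <- (va + vb)^2 /
      (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
    list(t = t, df = df, p = 2 * pt(-abs(t), df))
  }
  withr::with_seed(7, {
    for (i in 1:10) {
      a <- rnorm(sample(5:40, 1), sd = runif(1, 0.5, 2))
      b <- rnorm(sample(5:40, 1), mean = runif(1, -1, 1))
      got <- welchTTest(a, b)
      want <- directWelch(a, b)
      expect_equal(got$t, want$t, tolerance = 1e-10)
      expect_equal(got$df, want$df, tolerance = 1e-10)
      expect_equal(got$p, want$p, tolerance = 1e-10)
    }
  })

  expect_error(welchTTest(1, c(1, 2)), class = "npcStatsError")
  expect_error(welchTTest(c(1, 1, 1), c(2, 2, 2)),
               class = "npcStatsError")
})

test_that("expression-independence check reports slope and correlation", {
  # expression level scales the whole cell's probe (rim, cytoplasm and
  # nucleoplasm alike); crowding concentrations stay fixed
  cells <- withr::with_seed(21, lapply(1:20, function(i) {
    dens <- runif(1, 1, 4)
    ph <- simulateInterphaseCell(
      cellPhantomConfig("peripheral", seed = i, noise = "poisson",
                        densityRim = 3 * dens, densityCyto = dens,
                        densityNucleus = 0.15 * dens))
    measureCell(ph$donor, ph$acceptor, segmentCell(ph$donor))
  }))
  chk <- expressionIndependenceCheck(cells)
  expect_lt(abs(chk$correlation), 0.3)

  # adversarial positive control: probe strictly proportional to
  # localization must be detected
  rigged <- lapply(1:10, function(i)
    new("CellMeasurement", cellId = as.character(i),
        probeNE = 0.1 * i, probeCyto = 1, relativeProbe = 0.1 * i,
        localizationNE = i, localizationCyto = 1,
        qcFlags = character()))
  expect_equal(expressionIndependenceCheck(rigged)$correlation, 1,
               tolerance = 1e-9)

  const <- lapply(1:6, function(i)
    new("CellMeasurement", cellId = as.character(i), probeNE = 1,
        probeCyto = 1, relativeProbe = 1, localizationNE = 5,
        localizationCyto = 1, qcFlags = character()))
  expect_error(expressionIndependenceCheck(const),
               class = "npcStatsError")
  expect_error(expressionIndependenceCheck(rigged[1:3]),
               class = "npcStatsError")
})

test_that("treatment comparison normalizes to the reference mean", {
  ref <- withr::with_seed(3, lapply(1:12, function(i) {
    ph <- simulateInterphaseCell(smallCellConfig("peripheral", seed = i,
                                                 noise = "poisson"))
    measureCell(ph$donor, ph$acceptor, segmentCell(ph$donor))
  }))
  sameCmp <- compareTreatments(ref, ref)
  expect_equal(sameCmp@relativeMean, 1, tolerance = 1e-12)
  expect_equal(sameCmp@pValue, 1, tolerance = 1e-12)

  treated <- withr::with_seed(4, lapply(1:12, function(i) {
    ph <- simulateInterphaseCell(
      smallCellConfig("peripheral", seed = 100 + i, noise = "poisson",
                      concRim = 320))
    measureCell(ph$donor, ph$acceptor, segmentCell(ph$donor))
  }))
  cmp <- compareTreatments(ref, treated)
  expect_lt(cmp@relativeMean, 1)
  expect_lt(cmp@pValue, 0.05)

  expect_error(compareTreatments(ref, list()), class = "npcStatsError")
})
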