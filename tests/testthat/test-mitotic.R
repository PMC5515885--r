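# Mitotic time-lapse quantification.

test_that("anaphase onset is detected frame-accurately", {
  for (onset in c(3L, 5L)) {
    tl <- simulateTimelapse(smallTimelapseConfig("early_assembler",
                                                 onsetFrame = onset))
    expect_identical(detectAnaphaseOnset(tl$chromosome), onset)
  }
})

test_that("a one-frame spurious split is ignored by the persistence rule", {
  tl <- simulateTimelapse(smallTimelapseConfig("early_assembler",
                                               onsetFrame = 5L))
  spoofed <- tl$chromosome
  spoofed[, , 2] <- tl$chromosome[, , 8]   # injected early split frame
  expect_identical(detectAnaphaseOnset(spoofed), 5L)
})

test_that("a single static mass yields an onset-not-found error", {
  tl <- simulateTimelapse(smallTimelapseConfig("early_assembler"))
  static <- tl$chromosome
  for (i in seq_len(dim(static)[3])) static[, , i] <- tl$chromosome[, , 1]
  expect_error(detectAnaphaseOnset(static), class = "npcOnsetError")
})

test_that("chromosome rim band follows the boundary geometry", {
  # circular mass: band area ~ perimeter x width
  n <- 128
  x <- matrix(seq_len(n), n, n); y <- t(x)
  r <- 30
  img <- matrix(100, n, n)
  img[(x - 64)^2 + (y - 64)^2 <= r^2] <- 700
  mk <- chromosomeRimMask(img, rimWidth = 3)
  expect_equal(sum(mk$rim), 2 * pi * r * 3, tolerance = 0.15)

  # two separated masses get two bands
  tl <- simulateTimelapse(smallTimelapseConfig("early_assembler"))
  last <- dim(tl$chromosome)[3]
  mkLast <- chromosomeRimMask(tl$chromosome[, , last], rimWidth = 3)
  comp <- EBImage::bwlabel(EBImage::Image(mkLast$rim * 1))
  expect_gte(max(comp), 2)

  # matches the manifest band
  truth <- regionLabels(manifestMasks(tl$manifest, last)) == 3L
  iou <- sum(mkLast$rim & truth) / sum(mkLast$rim | truth)
  expect_gte(iou, 0.7)

  expect_error(chromosomeRimMask(matrix(100, 16, 16)),
               class = "npcRegionError")
})

test_that("localizationSignal is the rim excess over cytoplasm", {
  rim <- matrix(FALSE, 10, 10); rim[3:4, 3:4] <- TRUE
  cyto <- matrix(FALSE, 10, 10); cyto[7:9, 7:9] <- TRUE
  img <- matrix(0, 10, 10)
  img[cyto] <- 200; img[rim] <- 200
  expect_equal(localizationSignal(img, rim, cyto, background = 100), 0)
  img[rim] <- 300   # rim = 2x cytoplasm after background subtraction
  expect_equal(localizationSignal(img, rim, cyto, background = 100), 1)
  img[rim] <- 40    # below cytoplasm: clipped at zero
  expect_equal(localizationSignal(img, rim, cyto, background = 100), 0)
  expect_error(localizationSignal(img, rim, cyto, background = 200),
               class = "npcUndefinedRatioError")
})

test_that("probe timecourse is 1 at onset and flat without a ramp", {
  tl <- simulateTimelapse(smallTimelapseConfig("early_assembler",
                                               concPlateau = 100))
  pr <- probeTimecourse(tl$donor, tl$acceptor, tl$chromosome,
                        onsetFrame = expectedValues(tl$manifest)$onsetFrame,
                        background = trueBackground(tl$manifest))
  expect_identical(pr[expectedValues(tl$manifest)$onsetFrame], 1)
  expect_lt(max(abs(pr - 1), na.rm = TRUE), 0.02)
  # while localization still rises
  tr <- quantifyTimelapse(tl$donor, tl$acceptor, tl$chromosome,
                          background = trueBackground(tl$manifest))
  expect_gt(max(tr@localization), 0.5)
})

test_that("probe plateau matches the quench-ratio oracle noise-free", {
  tl <- simulateTimelapse(smallTimelapseConfig("early_assembler"))
  ev <- expectedValues(tl$manifest)
  pr <- probeTimecourse(tl$donor, tl$acceptor, tl$chromosome,
                        onsetFrame = ev$onsetFrame,
                        background = trueBackground(tl$manifest))
  plateau <- mean(utils::tail(pr, 3))
  expect_equal(1 - plateau, ev$plateauProbeDrop, tolerance = 0.02)
  # full expected series reproduced
  expect_equal(pr, ev$probeSeries, tolerance = 0.02)
})

test_that("half-time extraction follows the midpoint convention", {
  t <- seq(0, 30, 2)
  # step series: midpoint-crossing convention gives 5.0
  expect_equal(extractHalfTime(as.numeric(t >= 6), t, "rise")@time, 5)

  ht <- extractHalfTime(1 - exp(-(log(2) / 3) * pmax(t - 1, 0)), t,
                        "rise")
  expect_equal(ht@time, 4, tolerance = 0.2)

  flat <- extractHalfTime(rep(1, length(t)), t, "rise")
  expect_false(flat@recoverable)
  expect_true(is.na(flat@time))

  falling <- extractHalfTime(exp(-0.2 * t), t, "fall")
  expect_equal(falling@time, -log(0.5 + 0.5 * exp(-0.2 * 30)) / 0.2,
               tolerance = 1)

  expect_error(extractHalfTime(c(1, 2), c(0, 2), "rise"),
               class = "npcStatsError")
})

test_that("image-pipeline half-times match the analytic kinetics", {
  for (preset in phantomPresets()$kinetic) {
    tl <- simulateTimelapse(smallTimelapseConfig(preset))
    tr <- quantifyTimelapse(tl$donor, tl$acceptor, tl$chromosome,
                            background = trueBackground(tl$manifest))
    ev <- expectedValues(tl$manifest)
    expect_identical(tr@onsetFrame, ev$onsetFrame)
    expect_equal(tr@halfTimes$localization@time, ev$halfMaxTime,
                 tolerance = 1 / ev$halfMaxTime, label = preset)
    expect_equal(tr@halfTimes$probe@time, ev$halfMaxTime,
                 tolerance = 1 / ev$halfMaxTime,
                 label = paste(preset, "probe"))
  }
})

test_that("early assemblers dissociate while crowding persists", {
  tl <- simulateTimelapse(smallTimelapseConfig("early_assembler"))
  tr <- quantifyTimelapse(tl$donor, tl$acceptor, tl$chromosome,
                          background = trueBackground(tl$manifest))
  post <- tr@times >= 0
  loc <- tr@localization[post]; pr <- tr@probe[post]
  peak <- which.max(loc)
  expect_lt(loc[length(loc)], 0.8 * loc[peak])          # decay after peak
  plateau <- mean(utils::tail(pr, 3))
  expect_lt(max(abs(pr[peak:length(pr)] / plateau - 1)), 0.05)
})

test_that("max-normalized localization is robust to expression level", {
  base <- simulateTimelapse(smallTimelapseConfig("pom121_like"))
  dbl <- simulateTimelapse(smallTimelapseConfig("pom121_like",
                                                plateauDensity = 6))
  trB <- quantifyTimelapse(base$donor, base$acceptor, base$chromosome,
                           background = trueBackground(base$manifest))
  trD <- quantifyTimelapse(dbl$donor, dbl$acceptor, dbl$chromosome,
                           background = trueBackground(dbl$manifest))
  post <- trB@times >= 4
  normB <- trB@localization[post] / max(trB@localization)
  normD <- trD@localization[post] / max(trD@localization)
  expect_lt(max(abs(normB - normD)), 0.1)
  # probe read-out unchanged by expression
  expect_lt(max(abs(trB@probe - trD@probe), na.rm = TRUE), 0.02)
})

test_that("chromosome area timecourse tracks decondensation", {
  static <- simulateTimelapse(smallTimelapseConfig("pom121_like"))
  ev <- expectedValues(static$manifest)
  areaS <- chromosomeAreaTimecourse(static$chromosome, ev$onsetFrame)
  expect_lt(max(abs(areaS[static$times >= 0] - 1)), 0.1)

  growing <- simulateTimelapse(smallTimelapseConfig(
    "pom121_like", decondensationGrowth = 1.5))
  evG <- expectedValues(growing$manifest)
  areaG <- chromosomeAreaTimecourse(growing$chromosome, evG$onsetFrame)
  post <- growing$times >= 0
  expect_equal(areaG[post], evG$areaSeries[post], tolerance = 0.1)

  gap <- static$chromosome
  gap[, , 2] <- 100                         # frame with no signal
  areaGap <- chromosomeAreaTimecourse(gap, ev$onsetFrame)
  expect_true(is.na(areaGap[2]))
})
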