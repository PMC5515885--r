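# Nuclear-envelope rim segmentation.

rimIoU <- function(masks, manifest) {
  est <- regionMask(masks, "rim")
  truth <- regionLabels(manifestMasks(manifest)) == 3L
  sum(est & truth) / sum(est | truth)
}

test_that("noise-free phantom rim is recovered accurately", {
  ph <- simulateInterphaseCell(cellPhantomConfig("peripheral",
                                                 noise = "none"))
  masks <- segmentCell(ph$donor)
  expect_gte(rimIoU(masks, ph$manifest), 0.8)
  # nucleus and cytoplasm land on the right regions
  lab <- regionLabels(manifestMasks(ph$manifest))
  expect_gt(mean(lab[regionMask(masks, "nucleus")] == 2L), 0.9)
  expect_gt(mean(lab[regionMask(masks, "cytoplasm")] == 1L), 0.95)
})

test_that("blank and flat images raise a segmentation failure", {
  expect_error(segmentCell(matrix(100, 128, 128)),
               class = "npcSegmentationError")
  blank <- withr::with_seed(1,
    matrix(rpois(128 * 128, 100), 128, 128))
  expect_error(segmentCell(blank), class = "npcSegmentationError")
})

test_that("noisy phantoms are segmented reliably across seeds", {
  ious <- vapply(1:20, function(s) {
    ph <- simulateInterphaseCell(cellPhantomConfig("peripheral",
                                                   seed = s))
    rimIoU(segmentCell(ph$donor), ph$manifest)
  }, numeric(1))
  expect_gte(sum(ious >= 0.7), 19)
})

test_that("segmentation is deterministic for fixed input", {
  ph <- simulateInterphaseCell(cellPhantomConfig("peripheral", seed = 3))
  expect_identical(regionLabels(segmentCell(ph$donor)),
                   regionLabels(segmentCell(ph$donor)))
})
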