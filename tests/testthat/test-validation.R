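test_that("threshold agreement counts steps on the grid", {
  g <- defaultAmplitudeGrid()

  # identical varying thresholds: perfect agreement and correlation
  a <- BundleThresholds(1:4, c(5L, 9L, 13L, 20L), g)
  repA <- compareThresholds(a, a)
  expect_equal(repA@nCompared, 4L)
  expect_equal(repA@fractionWithinOneStep, 1)
  expect_equal(repA@fractionExact, 1)
  expect_equal(repA@pearsonR, 1)

  # worked example: [5, 6, 9] vs [5, 5, 5]
  d <- BundleThresholds(1:3, c(5L, 6L, 9L), g)
  r <- BundleThresholds(1:3, c(5L, 5L, 5L), g)
  rep2 <- compareThresholds(d, r)
  expect_equal(rep2@fractionWithinOneStep, 2 / 3)
  expect_equal(rep2@fractionExact, 1 / 3)

  # one side entirely not-found: nothing to compare
  none <- BundleThresholds(1:3, rep(NA_integer_, 3), g)
  rep3 <- compareThresholds(d, none)
  expect_equal(rep3@nCompared, 0L)
  expect_true(is.na(rep3@fractionWithinOneStep))
  expect_true(is.na(rep3@pearsonR))
  expect_equal(rep3@nDetectedOnly, 3L)

  # not-found electrodes are excluded from the compared set
  d4 <- BundleThresholds(1:3, c(5L, NA, 9L), g)
  r4 <- BundleThresholds(1:3, c(6L, 5L, NA), g)
  rep4 <- compareThresholds(d4, r4)
  expect_equal(rep4@nCompared, 1L)
  expect_equal(rep4@fractionWithinOneStep, 1)
  expect_equal(rep4@fractionExact, 0)
})

test_that("permutation baseline matches exhaustive enumeration", {
  g <- defaultAmplitudeGrid()
  idx <- c(5L, 9L, 13L, 17L, 21L)   # distinct, separated by > 1 step
  th <- BundleThresholds(1:5, idx, g)

  # exact expected chance agreement by enumerating all 120 permutations
  perms <- allPermutations(5L)
  exact <- mean(vapply(perms, function(p) mean(abs(idx[p] - idx) <= 1L),
                       numeric(1)))
  expect_equal(exact, 0.2)  # only fixed points fall within one step

  pb <- permutationBaseline(th, th, nPerm = 3000L, seed = 2L)
  expect_equal(pb$mean, exact, tolerance = 0.05)
  expect_lt(pb$mean, 1)

  # a constant reference is permutation-invariant
  thc <- BundleThresholds(1:4, rep(7L, 4), g)
  pbc <- permutationBaseline(thc, thc, nPerm = 50L, seed = 3L)
  expect_equal(pbc$fractions, rep(1, 50))
  expect_equal(pbc$sd, 0)

  # fixed seed reproduces the draw exactly
  pb2 <- permutationBaseline(th, th, nPerm = 100L, seed = 4L)
  pb3 <- permutationBaseline(th, th, nPerm = 100L, seed = 4L)
  expect_identical(pb2$fractions, pb3$fractions)
})

test_that("the repeats curve saturates and is reproducible", {
  cfg <- cleanConfig(12L, nRows = 6, nCols = 6)
  sim <- simulateScan(cfg)
  ref <- truthThresholds(sim$truth)
  config <- DetectionConfig()

  expect_error(repeatsCurve(sim$scan, config, c(1, 5), reference = ref),
               "below 2")
  expect_error(repeatsCurve(sim$scan, config, 40, reference = ref), "exceed")

  curve <- repeatsCurve(sim$scan, config, c(3L, 10L, 25L), nDraws = 4L,
                        seed = 6L, reference = ref)
  expect_equal(curve$nRepeats, c(3L, 10L, 25L))
  # accuracy rises sharply from very few repeats and levels off
  expect_lte(curve$meanWithinOneStep[1], curve$meanWithinOneStep[3] + 1e-9)

  # the full repeat count reproduces full-data detection in every draw
  full <- compareThresholds(runDetection(sim$scan, config), ref)
  expect_equal(curve$meanWithinOneStep[3], full@fractionWithinOneStep)
  expect_equal(curve$sdWithinOneStep[3], 0)

  curve2 <- repeatsCurve(sim$scan, config, c(3L, 10L, 25L), nDraws = 4L,
                         seed = 6L, reference = ref)
  expect_identical(attr(curve, "draws"), attr(curve2, "draws"))
})

test_that("the p-value sweep is flat near 0.05 and degenerates as p -> 1", {
  cfg <- cleanConfig(14L, nRows = 6, nCols = 6)
  sim <- simulateScan(cfg)
  ref <- truthThresholds(sim$truth)
  config <- DetectionConfig()

  expect_error(pvalueSweep(sim$scan, config, c(0.05, 1.2), ref), "\\(0, 1\\)")

  sweep <- pvalueSweep(sim$scan, config, c(0.02, 0.05, 0.08), ref)
  # the sweep entry at the default level reproduces the default run
  full <- compareThresholds(runDetection(sim$scan, config), ref)
  expect_equal(sweep$fractionWithinOneStep[sweep$pValue == 0.05],
               full@fractionWithinOneStep)
  expect_equal(sweep$fractionExact[sweep$pValue == 0.05], full@fractionExact)
  # robustness across the 0.02-0.08 band
  expect_lte(max(sweep$fractionWithinOneStep) - min(sweep$fractionWithinOneStep),
             0.1)

  # large p flags nearly everything: thresholds collapse toward the
  # lowest analyzed amplitude
  loose <- thresholdIndices(runDetection(sim$scan, DetectionConfig(pValue = 0.999)))
  strict <- thresholdIndices(runDetection(sim$scan, config))
  loose[is.na(loose)] <- Inf
  strict[is.na(strict)] <- Inf
  expect_true(all(loose <= strict))
  expect_lte(median(loose), 3)
})
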