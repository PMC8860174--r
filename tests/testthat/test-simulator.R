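test_that("simulation is deterministic in the seed", {
  cfg <- SimulationConfig(nRows = 4, nCols = 4, nRepeats = 5,
                          grid = defaultAmplitudeGrid(8, aMin = 0.3),
                          thresholdIndexRange = c(3L, 6L),
                          stimElectrodes = c(6L, 11L), seed = 21L)
  a <- simulateScan(cfg)
  b <- simulateScan(cfg)
  expect_identical(voltages(a$scan), voltages(b$scan))
  expect_identical(a$truth@thresholdIndex, b$truth@thresholdIndex)

  cfg2 <- SimulationConfig(nRows = 4, nCols = 4, nRepeats = 5,
                           grid = defaultAmplitudeGrid(8, aMin = 0.3),
                           thresholdIndexRange = c(3L, 6L),
                           stimElectrodes = c(6L, 11L), seed = 22L)
  expect_false(identical(voltages(a$scan), voltages(simulateScan(cfg2)$scan)))
  expect_identical(dim(voltages(a$scan)), dim(voltages(simulateScan(cfg2)$scan)))

  expect_identical(simulateBlock(cfg, 6L), simulateBlock(cfg, 6L))
})

test_that("ground truth is on-grid, bidirectional and monotone", {
  cfg <- SimulationConfig(nRows = 8, nCols = 8, nRepeats = 6,
                          grid = defaultAmplitudeGrid(12, aMin = 0.3),
                          thresholdIndexRange = c(4L, 10L), seed = 13L)
  sim <- simulateScan(SimulationConfig(nRows = 8, nCols = 8, nRepeats = 6,
                                       grid = defaultAmplitudeGrid(12, aMin = 0.3),
                                       thresholdIndexRange = c(4L, 10L),
                                       stimElectrodes = 1:16, seed = 13L))
  gt <- sim$truth
  arr <- electrodeArray(sim$scan)
  g <- amplitudes(gt@grid)

  # thresholds are grid members within the configured range
  expect_true(all(gt@thresholdIndex >= 4L & gt@thresholdIndex <= 11L))
  expect_equal(gt@thresholdAmplitude, g[gt@thresholdIndex])

  # bidirectional propagation: every axon path touches >= 2 borders, and
  # electrodes sit on both sides of the stimulation site
  for (i in seq_along(gt@electrode)) {
    path <- gt@pathElectrodes[[i]]
    expect_gte(bordersTouched(path, arr), 2L)
    expect_true(gt@electrode[i] %in% path)
  }

  # per-repeat activation is non-decreasing in amplitude (shared-uniform
  # coupling), and the probability at threshold reaches the truth level
  for (es in gt@electrode[1:4]) {
    act <- activationOutcomes(gt, es)
    expect_true(all(apply(act, 2, function(x) all(diff(x) >= 0))))
  }
  i <- 1L
  expect_gte(gt@activationProb[i, gt@thresholdIndex[i]], 0.5)
  if (gt@thresholdIndex[i] > 1L)
    expect_lt(gt@activationProb[i, gt@thresholdIndex[i] - 1L], 0.5)
})

test_that("evoked latency grows linearly with distance along the path", {
  cfg <- SimulationConfig(nRows = 8, nCols = 8, nRepeats = 6,
                          grid = defaultAmplitudeGrid(12, aMin = 0.3),
                          thresholdIndexRange = c(4L, 8L),
                          activationSlope = 0, jitterMs = 0, spontRate = 0,
                          noiseSd = 1, stimElectrodes = c(28L, 36L), seed = 4L)
  sim <- simulateScan(cfg)
  gt <- sim$truth
  arr <- electrodeArray(sim$scan)
  for (i in seq_along(gt@electrode)) {
    es <- gt@electrode[i]
    path <- gt@pathElectrodes[[i]]
    # reconstruct the along-path distance from the stored orientation
    rel <- sweep(positions(arr)[path, , drop = FALSE], 2, positions(arr)[es, ])
    dAlong <- abs(rel[, 1] * cos(gt@orientation[i]) + rel[, 2] * sin(gt@orientation[i]))
    expected <- round((0.5 + dAlong / 1000 / 1) * 20) + 1
    t <- simulateSpikeTimes(cfg, es, 12L)
    for (r in seq_len(nrow(t)))
      expect_equal(as.numeric(t[r, path]), pmin(41, pmax(7, expected)))
  }
})

test_that("the fast spike-time path matches the null and jitter models", {
  cfg <- SimulationConfig(nRows = 6, nCols = 6, nRepeats = 30,
                          grid = defaultAmplitudeGrid(10, aMin = 0.3),
                          thresholdIndexRange = c(3L, 7L),
                          activationSlope = 0, jitterMs = 0, seed = 17L)
  gt <- simulateScan(cfg)$truth
  i <- match(15L, gt@electrode)
  gtPath <- gt@pathElectrodes[[i]]

  # zero jitter: zero variance across repeats at path electrodes when active
  t <- simulateSpikeTimes(cfg, 15L, 10L)
  expect_equal(unname(apply(t[, gtPath, drop = FALSE], 2, var)),
               rep(0, length(gtPath)))

  # off-path electrodes behave like the uniform-timing null
  off <- setdiff(seq_len(36L), gtPath)
  draws <- as.vector(t[, off])
  for (a in c(2L, 5L)) draws <- c(draws, as.vector(simulateSpikeTimes(cfg, 15L, a)[, off]))
  expect_gte(min(draws), 7L)
  expect_lte(max(draws), 41L)
  expect_equal(mean(draws), 24, tolerance = 0.05)
  expect_equal(var(draws), 102, tolerance = 0.1)
})

test_that("a somatic cluster alone does not trip the border rule", {
  # for interior stimulating electrodes (cluster fully off the borders),
  # adding a strong local somatic response must leave detection untouched:
  # the flagged cluster gains only interior electrodes
  interior <- c(19L, 28L, 37L, 46L)  # diagonal of the 8 x 8 interior
  mk <- function(somatic) SimulationConfig(
    nRows = 8, nCols = 8, nRepeats = 10,
    grid = defaultAmplitudeGrid(12, aMin = 0.3),
    thresholdIndexRange = c(6L, 9L), spikeAmplitude = 0,
    somaticAmplitude = somatic, seed = 23L, stimElectrodes = interior)
  detOn <- runDetection(simulateScan(mk(150))$scan)
  detOff <- runDetection(simulateScan(mk(0))$scan)
  expect_identical(thresholdIndices(detOn), thresholdIndices(detOff))

  # with the axonal component restored, the somatic cluster (threshold
  # fraction 0.6) must not pull the detected threshold below truth
  cfg2 <- SimulationConfig(nRows = 8, nCols = 8, nRepeats = 25,
                           grid = defaultAmplitudeGrid(12, aMin = 0.3),
                           thresholdIndexRange = c(6L, 9L),
                           activationSlope = 0, jitterMs = 0, spontRate = 0,
                           noiseSd = 1, somaticAmplitude = 150, seed = 23L,
                           stimElectrodes = 28L)
  sim2 <- simulateScan(cfg2)
  det2 <- runDetection(sim2$scan)
  expect_equal(unname(thresholdIndices(det2)[1]),
               unname(sim2$truth@thresholdIndex[1]))
})

test_that("oversized configurations are refused with streaming advice", {
  expect_error(simulateScan(validationConfig(1L)), "runValidationStudy")
})
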