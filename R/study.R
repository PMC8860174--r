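#' Streaming synthetic validation study
#'
#' Generates a synthetic scan one stimulating electrode at a time and runs
#' the full detection pipeline on each electrode's block as it is
#' produced, so scans far larger than memory (e.g. all 256 electrodes of
#' the packaged 16 x 16 validation configuration, whose full tensor would
#' hold ~2.7e9 voltage samples) can be analyzed on a desk machine. Spike
#' times are extracted once per electrode; detection is then evaluated on
#' the full repeat set and, optionally, on random repeat subsets (the
#' subsets are drawn once and shared across electrodes, so each draw is a
#' coherent scan-wide rerun).
#'
#' @param simConfig a [SimulationConfig-class]; its seed drives all
#'   simulation randomness.
#' @param detConfig a [DetectionConfig-class].
#' @param subsetSizes integer vector of repeat-subset sizes to also
#'   evaluate (default none).
#' @param nSubsetDraws random subset draws per size.
#' @param subsetSeed seed for the subset draws (default: derived from the
#'   simulation seed).
#' @param verbose print one progress line per 32 electrodes.
#' @return list with elements `truth` ([GroundTruth-class]), `thresholds`
#'   (full-repeat [BundleThresholds-class]), `subsets` (nested list:
#'   per size, per draw, a [BundleThresholds-class]), `agreement` (the
#'   [AgreementReport-class] of the full run against ground truth), and
#'   `subsetAgreement` (data frame of per-draw fractions).
#' @examples
#' \donttest{
#' study <- runValidationStudy(SimulationConfig(nRows = 8, nCols = 8,
#'   grid = defaultAmplitudeGrid(20), thresholdIndexRange = c(8L, 16L),
#'   seed = 1L))
#' study$agreement
#' }
#' @export
runValidationStudy <- function(simConfig = validationConfig(),
                               detConfig = DetectionConfig(),
                               subsetSizes = integer(0),
                               nSubsetDraws = 10L,
                               subsetSeed = simConfig@seed + 1L,
                               verbose = FALSE) {
  validObject(simConfig); validObject(detConfig)
  array <- ElectrodeArray(simConfig@nRows, simConfig@nCols, simConfig@pitch)
  params <- .scanParams(simConfig)
  grid <- simConfig@grid
  S <- length(params$stim)
  R <- simConfig@nRepeats
  win <- windowSamples(detConfig, simConfig@samplingRate)
  subsetSizes <- as.integer(subsetSizes)
  if (any(subsetSizes < 2L) || any(subsetSizes > R))
    stop("subset sizes must lie in 2..nRepeats")
  draws <- withr::with_seed(as.integer(subsetSeed), {
    lapply(subsetSizes, function(k)
      lapply(seq_len(nSubsetDraws), function(j) sort(sample.int(R, k))))
  })
  full <- integer(S)
  sub <- lapply(subsetSizes, function(k) matrix(NA_integer_, S, nSubsetDraws))
  for (i in seq_len(S)) {
    block <- .simulateBlockRaw(simConfig, params$stim[i], params, array)
    times <- .blockSpikeTimes(block, detConfig, simConfig@samplingRate)
    ai <- attr(times, "ampIndices")
    full[i] <- .detectFromTimes(times, ai, array, grid, detConfig, length(win))
    for (si in seq_along(subsetSizes)) {
      for (j in seq_len(nSubsetDraws)) {
        sub[[si]][i, j] <- .detectFromTimes(times, ai, array, grid, detConfig,
                                            length(win),
                                            repeats = draws[[si]][[j]])
      }
    }
    if (verbose && i %% 32L == 0L)
      message("  analyzed ", i, "/", S, " stimulating electrodes")
  }
  truth <- .makeGroundTruth(simConfig, params, array)
  thresholds <- BundleThresholds(params$stim, full, grid)
  ref <- truthThresholds(truth)
  subsets <- lapply(seq_along(subsetSizes), function(si)
    lapply(seq_len(nSubsetDraws), function(j)
      BundleThresholds(params$stim, sub[[si]][, j], grid)))
  names(subsets) <- as.character(subsetSizes)
  subsetAgreement <- NULL
  if (length(subsetSizes)) {
    subsetAgreement <- do.call(rbind, lapply(seq_along(subsetSizes), function(si) {
      f <- vapply(subsets[[si]], function(bt)
        compareThresholds(bt, ref)@fractionWithinOneStep, numeric(1L))
      data.frame(nRepeats = subsetSizes[si], draw = seq_len(nSubsetDraws),
                 fractionWithinOneStep = f)
    }))
  }
  list(truth = truth,
       thresholds = thresholds,
       subsets = subsets,
       agreement = compareThresholds(thresholds, ref),
       subsetAgreement = subsetAgreement)
}
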