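# Independent oracles and small builders used across the suite.

# brute-force border count straight from electrode coordinates
bruteBordersTouched <- function(electrodes, arr) {
  if (length(electrodes) == 0L) return(0L)
  pos <- positions(arr)
  xs <- pos[electrodes, 1L]
  ys <- pos[electrodes, 2L]
  xmax <- max(pos[, 1L]); ymax <- max(pos[, 2L])
  sum(any(xs == 0), any(xs == xmax), any(ys == 0), any(ys == ymax))
}

# brute-force pruning: intersection with all higher amplitudes at once
brutePrune <- function(signal) {
  A <- length(signal)
  lapply(seq_len(A), function(j)
    sort(Reduce(intersect, signal[j:A])))
}

# all permutations of 1..n (for exhaustive permutation-baseline checks)
allPermutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in allPermutations(n - 1L)) {
    for (k in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
    }
  }
  out
}

# a small moderate-noise synthetic scan shared by invariance tests
smallScan <- function(seed = 5L) {
  simulateScan(SimulationConfig(
    nRows = 6, nCols = 6, nRepeats = 8,
    grid = defaultAmplitudeGrid(12, aMin = 0.3),
    thresholdIndexRange = c(4L, 9L), seed = seed))
}

# clean conditions: step activation, no jitter, no spontaneous spikes, no
# artifact, and a 1 uV noise floor far below the 60 uV spike (the variance
# test needs a noise floor to randomize silent electrodes' argmin)
cleanConfig <- function(seed = 2L, nRows = 8, nCols = 8) {
  SimulationConfig(nRows = nRows, nCols = nCols, nRepeats = 25,
                   grid = defaultAmplitudeGrid(20, aMin = 0.2),
                   thresholdIndexRange = c(5L, 16L),
                   activationSlope = 0, jitterMs = 0, spontRate = 0,
                   artifactAmplitude = 0, noiseSd = 1, seed = seed)
}

rebuildScan <- function(scan, v) {
  ScanRecording(v, samplingRate = samplingRate(scan),
                grid = amplitudeGrid(scan), array = electrodeArray(scan),
                stimElectrodes = stimElectrodes(scan))
}
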