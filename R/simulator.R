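#' Construct a simulation configuration
#'
#' All arguments default to the packaged validation conditions; see
#' [SimulationConfig-class] for the meaning and units of each parameter
#' and the package vignette for the rationale. Every random draw of the
#' simulator flows from `seed`.
#'
#' @param nRows,nCols,pitch array geometry.
#' @param samplingRate,nSamples,nRepeats recording layout.
#' @param grid an [AmplitudeGrid-class].
#' @param stimElectrodes stimulating electrodes (default: all electrodes).
#' @param seed integer master seed.
#' @param spikeAmplitude,spikeWidthMs,conductionVelocity,baseLatencyMs,jitterMs,captureRadiusUm
#'   evoked axonal component.
#' @param thresholdIndexRange,activationSlope,truthLevel activation curve.
#' @param artifactAmplitude,artifactTauMs,artifactFreqHz stimulation
#'   artifact component.
#' @param spontRate,spontAmplitude spontaneous component.
#' @param noiseSd recording noise.
#' @param somaticAmplitude,somaticRadiusUm,somaticThresholdFraction,somaticLatencyMs
#'   optional local somatic component (disabled when amplitude is 0).
#' @return a [SimulationConfig-class].
#' @export
SimulationConfig <- function(nRows = 16, nCols = 16, pitch = 60,
                             samplingRate = 20000, nSamples = 41, nRepeats = 25,
                             grid = defaultAmplitudeGrid(),
                             stimElectrodes = seq_len(nRows * nCols),
                             seed = 1L,
                             spikeAmplitude = 60, spikeWidthMs = 0.05,
                             conductionVelocity = 1, baseLatencyMs = 0.5,
                             jitterMs = 0.05, captureRadiusUm = 45,
                             thresholdIndexRange = c(14L, 36L),
                             activationSlope = 0.015, truthLevel = 0.5,
                             artifactAmplitude = 1000, artifactTauMs = 0.05,
                             artifactFreqHz = 2000,
                             spontRate = 10, spontAmplitude = 80,
                             noiseSd = 10,
                             somaticAmplitude = 0, somaticRadiusUm = 75,
                             somaticThresholdFraction = 0.6,
                             somaticLatencyMs = 0.35) {
  new("SimulationConfig",
      nRows = as.integer(nRows), nCols = as.integer(nCols),
      pitch = as.numeric(pitch), samplingRate = as.numeric(samplingRate),
      nSamples = as.integer(nSamples), nRepeats = as.integer(nRepeats),
      grid = grid, stimElectrodes = as.integer(stimElectrodes),
      seed = as.integer(seed),
      spikeAmplitude = as.numeric(spikeAmplitude),
      spikeWidthMs = as.numeric(spikeWidthMs),
      conductionVelocity = as.numeric(conductionVelocity),
      baseLatencyMs = as.numeric(baseLatencyMs),
      jitterMs = as.numeric(jitterMs),
      captureRadiusUm = as.numeric(captureRadiusUm),
      thresholdIndexRange = as.integer(thresholdIndexRange),
      activationSlope = as.numeric(activationSlope),
      truthLevel = as.numeric(truthLevel),
      artifactAmplitude = as.numeric(artifactAmplitude),
      artifactTauMs = as.numeric(artifactTauMs),
      artifactFreqHz = as.numeric(artifactFreqHz),
      spontRate = as.numeric(spontRate),
      spontAmplitude = as.numeric(spontAmplitude),
      noiseSd = as.numeric(noiseSd),
      somaticAmplitude = as.numeric(somaticAmplitude),
      somaticRadiusUm = as.numeric(somaticRadiusUm),
      somaticThresholdFraction = as.numeric(somaticThresholdFraction),
      somaticLatencyMs = as.numeric(somaticLatencyMs))
}

#' The packaged validation configuration
#'
#' The default synthetic study conditions used by the package's validation
#' experiments: a 16 x 16 array at 60 um pitch, the standard 40-level 10%
#' geometric amplitude grid, 25 repeats at 20 kHz, every electrode
#' stimulated, with moderate noise, latency jitter and spontaneous
#' activity. Identical to `SimulationConfig()` with the given seed.
#'
#' @param seed integer master seed.
#' @return a [SimulationConfig-class].
#' @export
validationConfig <- function(seed = 1L) SimulationConfig(seed = seed)

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0("SimulationConfig: %d x %d array, %d amplitudes, %d repeats, ",
                     "%d stim electrodes, seed %d\n"),
              object@nRows, object@nCols, length(object@grid@amplitudes),
              object@nRepeats, length(object@stimElectrodes), object@seed))
  cat(sprintf("  spike %g uV (jitter %g ms), noise sd %g uV, spontaneous %g Hz\n",
              object@spikeAmplitude, object@jitterMs, object@noiseSd,
              object@spontRate))
})

# Scan-level random parameters, drawn once from the master seed in a fixed
# order: axon orientations, true threshold indices, per-repeat coupling
# uniforms, per-electrode sub-seeds for the trace-level draws.
.scanParams <- function(config) {
  stim <- config@stimElectrodes
  S <- length(stim)
  R <- config@nRepeats
  lo <- config@thresholdIndexRange[1L]
  hi <- config@thresholdIndexRange[2L]
  withr::with_seed(config@seed, {
    orientation <- runif(S, 0, pi)
    tidx <- if (lo == hi) rep(lo, S) else sample(lo:hi, S, replace = TRUE)
    u <- matrix(runif(S * R), S, R)
    subseed <- sample.int(.Machine$integer.max - 1L, S)
  })
  amps <- config@grid@amplitudes
  prob <- matrix(0, S, length(amps))
  for (i in seq_len(S)) {
    if (config@activationSlope == 0) {
      prob[i, ] <- as.numeric(amps >= amps[tidx[i]])
    } else {
      # logistic in log-amplitude, centred half a grid step below the
      # drawn threshold level so that level itself sits high on the curve
      centre <- exp((log(amps[tidx[i] - 1L]) + log(amps[tidx[i]])) / 2)
      prob[i, ] <- plogis((log(amps) - log(centre)) / config@activationSlope)
    }
  }
  truthIdx <- apply(prob, 1L, function(p) {
    w <- which(p >= config@truthLevel)
    if (length(w)) w[1L] else NA_integer_
  })
  list(stim = stim, orientation = orientation, drawnIndex = tidx,
       truthIndex = as.integer(truthIdx), prob = prob, u = u,
       subseed = subseed)
}

# Electrodes within captureRadius of the axon line through the stimulation
# site, plus signed distances along the line (bidirectional propagation
# uses the absolute value).
.axonPath <- function(config, array, es, theta) {
  p0 <- array@positions[es, ]
  rel <- sweep(array@positions, 2L, p0)
  dAlong <- rel[, 1L] * cos(theta) + rel[, 2L] * sin(theta)
  dPerp <- abs(-rel[, 1L] * sin(theta) + rel[, 2L] * cos(theta))
  onPath <- which(dPerp <= config@captureRadiusUm)
  list(electrodes = onPath, dAlong = dAlong[onPath])
}

# Raw voltage block for one stimulating electrode: array (A, R, E, T), uV.
.simulateBlockRaw <- function(config, es, params, array) {
  i <- match(as.integer(es), params$stim)
  if (is.na(i)) stop("electrode ", es, " is not a stimulating electrode of this config")
  A <- length(config@grid@amplitudes)
  E <- nElectrodes(array)
  T <- config@nSamples
  R <- config@nRepeats
  fs <- config@samplingRate
  amps <- config@grid@amplitudes
  path <- .axonPath(config, array, es, params$orientation[i])
  nPath <- length(path$electrodes)
  somIdx <- integer(0)
  if (config@somaticAmplitude > 0) {
    dist0 <- sqrt(rowSums(sweep(array@positions, 2L, array@positions[es, ])^2))
    somIdx <- which(dist0 <= config@somaticRadiusUm)
  }
  # draw order is fixed, optional components last, so that disabling a
  # later component leaves the earlier draws (noise, spontaneous spikes)
  # bit-identical
  withr::with_seed(params$subseed[i], {
    block <- array(if (config@noiseSd > 0) rnorm(A * E * T * R, 0, config@noiseSd)
                   else 0, c(A, E, T, R))
    lam <- config@spontRate * (T / fs) * A * E * R
    nEv <- if (lam > 0) rpois(1L, lam) else 0L
    if (nEv > 0L) {
      evA <- sample.int(A, nEv, replace = TRUE)
      evE <- sample.int(E, nEv, replace = TRUE)
      evR <- sample.int(R, nEv, replace = TRUE)
      evT <- runif(nEv, 0, T - 1)
    }
    jit <- matrix(rnorm(nPath * R, 0, config@jitterMs), nPath, R)
    jitSom <- if (length(somIdx))
      matrix(rnorm(length(somIdx) * R, 0, config@jitterMs), length(somIdx), R)
    else NULL
  })
  # stimulation artifact: damped oscillation, amplitude-scaled, spatially
  # attenuated; decays before the analysis window opens
  tms <- (seq_len(T) - 1L) / fs * 1000
  shape <- exp(-tms / config@artifactTauMs) * cos(2 * pi * config@artifactFreqHz * tms / 1000)
  dist <- sqrt(rowSums(sweep(array@positions, 2L, array@positions[es, ])^2))
  spatial <- 1 / (1 + (dist / config@pitch)^2)
  if (config@artifactAmplitude > 0) {
    art <- (config@artifactAmplitude * amps / max(amps)) %o% spatial %o% shape
    block <- block + as.vector(art)
    dim(block) <- c(A, E, T, R)
  }
  sigmaS <- config@spikeWidthMs * fs / 1000
  t0 <- seq_len(T) - 1L
  # evoked axonal spikes: bidirectional propagation along the path
  if (config@spikeAmplitude > 0 && nPath > 0L) {
    act <- outer(params$prob[i, ], params$u[i, ], ">=")  # (A, R)
    c0 <- config@baseLatencyMs + abs(path$dAlong) / 1000 / config@conductionVelocity
    for (r in seq_len(R)) {
      aset <- which(act[, r])
      if (!length(aset)) next
      ce <- (c0 + jit[, r]) * fs / 1000
      W <- -config@spikeAmplitude * exp(-0.5 * (outer(ce, t0, "-") / sigmaS)^2)
      block[aset, path$electrodes, , r] <-
        block[aset, path$electrodes, , r] + rep(W, each = length(aset))
    }
  }
  # optional somatic component: local, unidirectional, lower threshold
  if (config@somaticAmplitude > 0 && length(somIdx)) {
    truthAmp <- amps[params$truthIndex[i]]
    asetSom <- which(amps >= config@somaticThresholdFraction * truthAmp)
    if (length(asetSom)) for (r in seq_len(R)) {
      ce <- (config@somaticLatencyMs + jitSom[, r]) * fs / 1000
      W <- -config@somaticAmplitude * exp(-0.5 * (outer(ce, t0, "-") / sigmaS)^2)
      block[asetSom, somIdx, , r] <-
        block[asetSom, somIdx, , r] + rep(W, each = length(asetSom))
    }
  }
  # spontaneous spikes at uniform times, independent across trials
  if (config@spontRate > 0 && nEv > 0L) {
    for (off in -3L:3L) {
      s <- round(evT) + off
      keep <- s >= 0 & s <= T - 1
      if (!any(keep)) next
      w <- -config@spontAmplitude * exp(-0.5 * ((s[keep] - evT[keep]) / sigmaS)^2)
      lin <- evA[keep] + A * (evE[keep] - 1L) + A * E * s[keep] +
        A * E * T * (evR[keep] - 1L)
      block[lin] <- block[lin] + w
    }
  }
  aperm(block, c(1L, 4L, 2L, 3L))  # -> (A, R, E, T)
}

#' Simulate the raw voltage block of one stimulating electrode
#'
#' Generates the (amplitude, repeat, recording electrode, sample) voltage
#' tensor for a single stimulating electrode of a synthetic scan,
#' bit-reproducibly and independently of the other electrodes, which
#' allows scan-scale detection to stream one stimulating electrode at a
#' time (see [runValidationStudy()]).
#'
#' @param config a [SimulationConfig-class].
#' @param es stimulating electrode index.
#' @return numeric array (amplitude, repeat, recording electrode, sample)
#'   in uV.
#' @export
simulateBlock <- function(config, es) {
  validObject(config)
  array <- ElectrodeArray(config@nRows, config@nCols, config@pitch)
  .simulateBlockRaw(config, es, .scanParams(config), array)
}

.makeGroundTruth <- function(config, params, array) {
  paths <- lapply(seq_along(params$stim), function(i)
    .axonPath(config, array, params$stim[i], params$orientation[i])$electrodes)
  new("GroundTruth",
      electrode = params$stim,
      thresholdIndex = params$truthIndex,
      thresholdAmplitude = ifelse(is.na(params$truthIndex), NA_real_,
                                  config@grid@amplitudes[params$truthIndex]),
      orientation = params$orientation,
      pathElectrodes = paths,
      activationProb = params$prob,
      couplingU = params$u,
      grid = config@grid)
}

#' Simulate a synthetic stimulation scan with ground truth
#'
#' Generates a complete synthetic single-electrode stimulation scan as the
#' sum of four voltage components: evoked axonal activity (a straight axon
#' path through each stimulation site at a random orientation, conducting
#' bidirectionally at `conductionVelocity`, with per-trial activation
#' drawn from a monotone activation curve through one shared uniform per
#' repeat), the stimulation artifact, spontaneous Poisson spikes, and
#' Gaussian noise. The ground truth records each stimulating electrode's
#' true bundle threshold (the lowest grid amplitude whose activation
#' probability reaches `truthLevel`), the axon-path membership, and the
#' activation model.
#'
#' The full tensor is materialized in memory, so this is intended for
#' desk-scale configurations; use [runValidationStudy()] to analyze large
#' configurations one stimulating electrode at a time.
#'
#' @param config a [SimulationConfig-class].
#' @return list with elements `scan` ([ScanRecording-class]) and `truth`
#'   ([GroundTruth-class]).
#' @examples
#' cfg <- SimulationConfig(nRows = 4, nCols = 4, nRepeats = 5,
#'                         grid = defaultAmplitudeGrid(12),
#'                         thresholdIndexRange = c(4L, 10L),
#'                         stimElectrodes = c(6L, 7L), seed = 7L)
#' sim <- simulateScan(cfg)
#' truthThresholds(sim$truth)
#' @export
simulateScan <- function(config) {
  validObject(config)
  array <- ElectrodeArray(config@nRows, config@nCols, config@pitch)
  params <- .scanParams(config)
  S <- length(params$stim)
  A <- length(config@grid@amplitudes)
  E <- nElectrodes(array)
  size <- as.numeric(S) * A * config@nRepeats * E * config@nSamples
  if (size > 2e8)
    stop("this configuration would materialize ", format(size, big.mark = ","),
         " voltage samples; use runValidationStudy() to stream it instead")
  v <- array(0, c(S, A, config@nRepeats, E, config@nSamples))
  for (i in seq_len(S))
    v[i, , , , ] <- .simulateBlockRaw(config, params$stim[i], params, array)
  scan <- ScanRecording(v, samplingRate = config@samplingRate,
                        grid = config@grid, array = array,
                        stimElectrodes = params$stim)
  list(scan = scan, truth = .makeGroundTruth(config, params, array))
}

#' Simulate spike times directly (fast path)
#'
#' Draws the per-repeat, per-recording-electrode spike times for one
#' stimulating electrode and amplitude without synthesizing waveforms:
#' electrodes on the axon path of an activated trial get the propagation
#' latency plus jitter (rounded to the sample grid and clamped to the
#' window); all other trials get a uniform draw over the window, matching
#' the argmin of pure noise. The timing model is distributionally
#' identical to running spike-time extraction on [simulateBlock()] output,
#' and is intended for statistical tests of the variance, pruning and
#' border steps.
#'
#' @param config a [SimulationConfig-class].
#' @param es stimulating electrode index.
#' @param a amplitude grid index.
#' @param window integer vector of 1-based window sample indices (default:
#'   the standard 0.3-2 ms window at the config's sampling rate).
#' @return integer matrix (repeat x recording electrode) of absolute
#'   sample indices.
#' @export
simulateSpikeTimes <- function(config, es, a,
                               window = windowSamples(DetectionConfig(),
                                                      config@samplingRate)) {
  validObject(config)
  array <- ElectrodeArray(config@nRows, config@nCols, config@pitch)
  params <- .scanParams(config)
  i <- match(as.integer(es), params$stim)
  if (is.na(i)) stop("electrode ", es, " is not a stimulating electrode of this config")
  a <- as.integer(a)
  stopifnot(a >= 1L, a <= length(config@grid@amplitudes))
  E <- nElectrodes(array)
  R <- config@nRepeats
  fs <- config@samplingRate
  path <- .axonPath(config, array, es, params$orientation[i])
  seed2 <- as.integer((as.numeric(params$subseed[i]) + 7919 * a) %% (.Machine$integer.max - 1L)) + 1L
  withr::with_seed(seed2, {
    t <- matrix(sample(window, R * E, replace = TRUE), R, E)
    active <- params$u[i, ] <= params$prob[i, a]
    if (any(active) && length(path$electrodes)) {
      c0 <- config@baseLatencyMs + abs(path$dAlong) / 1000 / config@conductionVelocity
      for (r in which(active)) {
        jit <- rnorm(length(c0), 0, config@jitterMs)
        smp <- round((c0 + jit) * fs / 1000) + 1L
        t[r, path$electrodes] <- pmin(max(window), pmax(min(window), smp))
      }
    }
  })
  storage.mode(t) <- "integer"
  t
}

#' Accessors for GroundTruth
#'
#' @param x a [GroundTruth-class].
#' @param electrode stimulating electrode index (for
#'   `activationOutcomes`).
#' @return `truthThresholds` returns the true thresholds as a
#'   [BundleThresholds-class]; `activationOutcomes` the (amplitude x
#'   repeat) logical activation matrix of one stimulating electrode.
#' @name GroundTruth-accessors
NULL

#' @rdname GroundTruth-accessors
#' @export
setMethod("truthThresholds", "GroundTruth", function(x) {
  BundleThresholds(x@electrode, x@thresholdIndex, x@grid)
})

#' @rdname GroundTruth-accessors
#' @export
setMethod("activationOutcomes", "GroundTruth", function(x, electrode) {
  i <- match(as.integer(electrode), x@electrode)
  if (is.na(i)) stop("electrode ", electrode, " has no ground truth")
  outer(x@activationProb[i, ], x@couplingU[i, ], ">=")
})

#' @rdname GroundTruth-accessors
#' @param row.names,optional,... conventional (unused).
#' @method as.data.frame GroundTruth
#' @export
as.data.frame.GroundTruth <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(stim_electrode = x@electrode,
             true_threshold_uA = x@thresholdAmplitude,
             true_index = x@thresholdIndex,
             orientation_rad = x@orientation,
             n_path_electrodes = lengths(x@pathElectrodes))
}

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d stimulating electrodes, thresholds %.3g - %.3g uA\n",
              length(object@electrode),
              min(object@thresholdAmplitude, na.rm = TRUE),
              max(object@thresholdAmplitude, na.rm = TRUE)))
})
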