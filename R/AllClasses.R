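#' @import methods
#' @importFrom stats qchisq rnorm runif rpois var cor plogis sd
NULL

#' Rectangular multi-electrode array geometry
#'
#' Represents a rectangular grid of extracellular electrodes: grid shape,
#' inter-electrode pitch, per-electrode planar coordinates, and the four
#' border sets (left, right, top, bottom) used by the bundle-detection
#' border rule. Electrodes are indexed 1-based in row-major order starting
#' at the top-left corner.
#'
#' @slot nRows,nCols integer grid dimensions (each at least 2).
#' @slot pitch numeric inter-electrode spacing in micrometres.
#' @slot positions numeric matrix (one row per electrode) of (x, y)
#'   coordinates in micrometres.
#' @slot borderSets named list of four integer vectors (\code{left},
#'   \code{right}, \code{top}, \code{bottom}) of electrode indices.
#'
#' @seealso [ElectrodeArray()] for construction, [bordersTouched()].
#' @export
setClass("ElectrodeArray",
  representation(
    nRows = "integer",
    nCols = "integer",
    pitch = "numeric",
    positions = "matrix",
    borderSets = "list"
  )
)

setValidity("ElectrodeArray", function(object) {
  msg <- character(0)
  n <- object@nRows * object@nCols
  if (object@nRows < 2L || object@nCols < 2L)
    msg <- c(msg, "nRows and nCols must both be >= 2 (borders degenerate otherwise)")
  if (length(object@pitch) != 1L || !is.finite(object@pitch) || object@pitch <= 0)
    msg <- c(msg, "pitch must be a single positive number")
  if (nrow(object@positions) != n || ncol(object@positions) != 2L)
    msg <- c(msg, sprintf("positions must be a %d x 2 matrix", n))
  if (anyDuplicated(object@positions) > 0L)
    msg <- c(msg, "electrode positions must be distinct")
  if (!identical(sort(names(object@borderSets)), sort(c("left", "right", "top", "bottom"))))
    msg <- c(msg, "borderSets must be named left, right, top, bottom")
  else {
    if (any(vapply(object@borderSets, length, 1L) == 0L))
      msg <- c(msg, "every border set must be non-empty")
    memb <- tabulate(unlist(object@borderSets), nbins = n)
    expected <- 2L * 4L + 2L * (object@nRows - 2L) + 2L * (object@nCols - 2L)
    if (sum(memb) != expected)
      msg <- c(msg, "border membership counts are inconsistent with the grid shape")
  }
  if (length(msg)) msg else TRUE
})

#' Stimulation amplitude grid
#'
#' An ordered set of stimulation current amplitudes in microamperes.
#' Amplitudes must be strictly increasing and positive; the first entry is
#' the lowest amplitude, which detection uses as the artifact reference.
#'
#' @slot amplitudes strictly increasing positive numeric vector (uA).
#' @seealso [AmplitudeGrid()], [defaultAmplitudeGrid()].
#' @export
setClass("AmplitudeGrid", representation(amplitudes = "numeric"))

setValidity("AmplitudeGrid", function(object) {
  a <- object@amplitudes
  if (length(a) < 2L) return("an amplitude grid needs at least 2 levels")
  if (!all(is.finite(a)) || any(a <= 0)) return("amplitudes must be finite and positive")
  if (any(diff(a) <= 0)) return("amplitudes must be strictly increasing")
  TRUE
})

#' Detection configuration
#'
#' Tunable parameters of the bundle-detection pipeline. The single model
#' hyperparameter is \code{pValue}, the level of the chi-squared spike-time
#' variance test; the remaining fields fix the analysis window, the border
#' rule, and optional recording-electrode exclusions.
#'
#' @slot pValue level of the variance hypothesis test, in (0, 1).
#' @slot windowStartMs,windowEndMs analysis window after stimulus onset, ms.
#' @slot minBorders minimum number of distinct array borders the activated
#'   set must touch (>= 2).
#' @slot excludeRecording integer indices of recording electrodes excluded
#'   from the signal sets.
#' @slot cornerRule \code{"literal"} (a lone corner electrode counts as two
#'   borders) or \code{"two-electrode"} (distinct electrodes required on
#'   distinct borders).
#' @seealso [DetectionConfig()], [runDetection()].
#' @export
setClass("DetectionConfig",
  representation(
    pValue = "numeric",
    windowStartMs = "numeric",
    windowEndMs = "numeric",
    minBorders = "integer",
    excludeRecording = "integer",
    cornerRule = "character"
  )
)

setValidity("DetectionConfig", function(object) {
  msg <- character(0)
  if (!(length(object@pValue) == 1L && is.finite(object@pValue) &&
        object@pValue > 0 && object@pValue < 1))
    msg <- c(msg, "pValue must be a single number in (0, 1)")
  if (!(object@windowStartMs >= 0 && object@windowStartMs < object@windowEndMs))
    msg <- c(msg, "need 0 <= windowStartMs < windowEndMs")
  if (object@minBorders < 2L)
    msg <- c(msg, "minBorders must be >= 2")
  if (!object@cornerRule %in% c("literal", "two-electrode"))
    msg <- c(msg, "cornerRule must be 'literal' or 'two-electrode'")
  if (length(msg)) msg else TRUE
})

#' Single-electrode stimulation scan
#'
#' A stimulation scan: the 5-D voltage record of repeated single-electrode
#' stimulation, indexed (stimulating electrode, amplitude, repeat,
#' recording electrode, time sample), together with its sampling rate,
#' amplitude grid and array geometry. Voltages are in microvolts; the
#' stimulus is delivered at the first time sample.
#'
#' @slot voltages 5-D numeric array, dims (stim, amplitude, repeat,
#'   recording electrode, sample), uV.
#' @slot samplingRate sampling rate in Hz.
#' @slot stimElectrodes integer electrode indices of the first dimension.
#' @slot grid an [AmplitudeGrid-class].
#' @slot array an [ElectrodeArray-class].
#' @seealso [ScanRecording()], [readScan()], [simulateScan()].
#' @export
setClass("ScanRecording",
  representation(
    voltages = "array",
    samplingRate = "numeric",
    stimElectrodes = "integer",
    grid = "AmplitudeGrid",
    array = "ElectrodeArray"
  )
)

setValidity("ScanRecording", function(object) {
  d <- dim(object@voltages)
  msg <- character(0)
  if (length(d) != 5L)
    return("voltages must be a 5-D array (stim, amplitude, repeat, recording, sample)")
  nEl <- object@array@nRows * object@array@nCols
  if (d[1L] != length(object@stimElectrodes))
    msg <- c(msg, sprintf("stim axis has length %d but %d stimElectrodes given",
                          d[1L], length(object@stimElectrodes)))
  if (any(object@stimElectrodes < 1L) || any(object@stimElectrodes > nEl))
    msg <- c(msg, "stimElectrodes out of range for the array")
  if (d[2L] != length(object@grid@amplitudes))
    msg <- c(msg, sprintf("amplitude axis has length %d but the grid has %d levels",
                          d[2L], length(object@grid@amplitudes)))
  if (d[3L] < 1L)
    msg <- c(msg, "empty repeats axis")
  if (d[4L] != nEl)
    msg <- c(msg, sprintf("recording axis has length %d but the array has %d electrodes",
                          d[4L], nEl))
  if (!(length(object@samplingRate) == 1L && is.finite(object@samplingRate) &&
        object@samplingRate > 0))
    msg <- c(msg, "samplingRate must be a single positive number")
  else {
    # the time axis must cover the upper analysis-window bound (2 ms)
    need <- floor(2e-3 * object@samplingRate) + 1L
    if (d[5L] < need)
      msg <- c(msg, sprintf("time axis has %d samples; at least %d needed to cover 2 ms",
                            d[5L], need))
  }
  if (anyNA(object@voltages) || any(!is.finite(object@voltages)))
    msg <- c(msg, "voltages contain non-finite values")
  if (length(msg)) msg else TRUE
})

#' Per-electrode bundle-activation thresholds
#'
#' The result of bundle detection: for each stimulating electrode either
#' the lowest grid amplitude whose activated electrode set touches the
#' required number of array borders, or an explicit not-found state
#' (\code{NA} index/amplitude, status \code{"not_found"}) when no tested
#' amplitude qualifies.
#'
#' @slot electrode integer stimulating-electrode indices.
#' @slot index integer amplitude-grid index of the threshold (NA if not
#'   found).
#' @slot amplitude numeric threshold amplitude in uA (NA if not found).
#' @slot grid the [AmplitudeGrid-class] the indices refer to.
#' @seealso [runDetection()], [writeThresholds()], [compareThresholds()].
#' @export
setClass("BundleThresholds",
  representation(
    electrode = "integer",
    index = "integer",
    amplitude = "numeric",
    grid = "AmplitudeGrid"
  )
)

setValidity("BundleThresholds", function(object) {
  n <- length(object@electrode)
  if (length(object@index) != n || length(object@amplitude) != n)
    return("electrode, index and amplitude must have equal length")
  amps <- object@grid@amplitudes
  ok <- is.na(object@index) | (object@index >= 1L & object@index <= length(amps))
  if (!all(ok)) return("threshold indices out of range of the amplitude grid")
  det <- !is.na(object@index)
  if (any(is.na(object@amplitude[det])))
    return("detected thresholds must carry an amplitude")
  if (any(abs(object@amplitude[det] - amps[object@index[det]]) >
          1e-9 * pmax(1, amps[object@index[det]])))
    return("threshold amplitudes must be members of the amplitude grid")
  if (any(!is.na(object@amplitude[!det])))
    return("not-found entries must have NA amplitude")
  TRUE
})

#' Synthetic stimulation-scan configuration
#'
#' Parameters of the synthetic scan generator. The generated voltage is the
#' sum of four components: evoked axonal activity (a straight axon path
#' through the stimulation site, conducting bidirectionally, with an
#' amplitude-dependent activation probability), the electrical stimulation
#' artifact (a damped oscillation, amplitude-scaled and spatially
#' attenuated), spontaneous Poisson spiking, and Gaussian noise. The
#' defaults are the packaged validation conditions; see the package
#' vignette for the rationale behind each value.
#'
#' @slot nRows,nCols array shape (default 16 x 16).
#' @slot pitch electrode pitch in um (60).
#' @slot samplingRate Hz (20000).
#' @slot nSamples trace length in samples (41, i.e. 2.05 ms).
#' @slot nRepeats stimulation repeats per amplitude (25).
#' @slot grid [AmplitudeGrid-class] (40 levels, 0.1 uA growing 10% per step).
#' @slot stimElectrodes integer stimulating electrodes (default: all).
#' @slot seed integer master seed; every random draw flows from it.
#' @slot spikeAmplitude magnitude of the negative axonal spike peak, uV (60).
#' @slot spikeWidthMs Gaussian spike half-width (sd), ms (0.05).
#' @slot conductionVelocity axonal conduction velocity, m/s (1).
#' @slot baseLatencyMs evoked latency at the stimulation site, ms (0.5).
#' @slot jitterMs sd of trial-to-trial latency jitter, ms (0.05).
#' @slot captureRadiusUm electrodes within this distance of the axon line
#'   record its spikes, um (45: the lateral spread of the recorded
#'   compound bundle signal; above half the pitch, so wherever the line
#'   crosses a border at least one border electrode is captured).
#' @slot thresholdIndexRange integer range of grid indices from which each
#'   stimulating electrode's true bundle threshold is drawn (14..36).
#' @slot activationSlope logistic scale of the activation curve in
#'   log-amplitude units (0.015); 0 gives a step activation curve.
#' @slot truthLevel activation probability defining the ground-truth
#'   threshold: the lowest grid amplitude with probability >= this level
#'   (0.5; a step curve makes this coincide with probability 1).
#' @slot artifactAmplitude artifact peak at the stimulating electrode for
#'   the top grid amplitude, uV (1000).
#' @slot artifactTauMs artifact decay time constant, ms (0.05).
#' @slot artifactFreqHz artifact oscillation frequency, Hz (2000).
#' @slot spontRate per-electrode spontaneous firing rate, Hz (10).
#' @slot spontAmplitude magnitude of spontaneous spike peaks, uV (80).
#' @slot noiseSd Gaussian recording noise sd, uV (10).
#' @slot somaticAmplitude magnitude of the local somatic spike component,
#'   uV (0 = disabled in the validation conditions).
#' @slot somaticRadiusUm radius of the somatic cluster around the
#'   stimulating electrode, um (75).
#' @slot somaticThresholdFraction somatic threshold as a fraction of the
#'   bundle threshold amplitude (0.6).
#' @slot somaticLatencyMs somatic spike latency, ms (0.35).
#' @seealso [SimulationConfig()], [simulateScan()], [runValidationStudy()].
#' @export
setClass("SimulationConfig",
  representation(
    nRows = "integer", nCols = "integer", pitch = "numeric",
    samplingRate = "numeric", nSamples = "integer", nRepeats = "integer",
    grid = "AmplitudeGrid", stimElectrodes = "integer", seed = "integer",
    spikeAmplitude = "numeric", spikeWidthMs = "numeric",
    conductionVelocity = "numeric", baseLatencyMs = "numeric",
    jitterMs = "numeric", captureRadiusUm = "numeric",
    thresholdIndexRange = "integer", activationSlope = "numeric",
    truthLevel = "numeric",
    artifactAmplitude = "numeric", artifactTauMs = "numeric",
    artifactFreqHz = "numeric",
    spontRate = "numeric", spontAmplitude = "numeric",
    noiseSd = "numeric",
    somaticAmplitude = "numeric", somaticRadiusUm = "numeric",
    somaticThresholdFraction = "numeric", somaticLatencyMs = "numeric"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character(0)
  if (object@nRows < 2L || object@nCols < 2L)
    msg <- c(msg, "array shape must be at least 2 x 2")
  if (object@nRepeats < 2L)
    msg <- c(msg, "nRepeats must be >= 2 (spike-time variance needs repeats)")
  if (object@jitterMs < 0) msg <- c(msg, "jitterMs must be >= 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@spontRate < 0) msg <- c(msg, "spontRate must be >= 0")
  if (object@activationSlope < 0) msg <- c(msg, "activationSlope must be >= 0")
  if (!(object@truthLevel > 0 && object@truthLevel <= 1))
    msg <- c(msg, "truthLevel must be in (0, 1]")
  nAmp <- length(object@grid@amplitudes)
  r <- object@thresholdIndexRange
  if (length(r) != 2L || r[1L] < 2L || r[2L] > nAmp || r[1L] > r[2L])
    msg <- c(msg, "thresholdIndexRange must lie within 2..length(grid)")
  nEl <- object@nRows * object@nCols
  if (length(object@stimElectrodes) &&
      (any(object@stimElectrodes < 1L) || any(object@stimElectrodes > nEl)))
    msg <- c(msg, "stimElectrodes out of range")
  need <- floor(2e-3 * object@samplingRate) + 1L
  if (object@nSamples < need)
    msg <- c(msg, sprintf("nSamples must be >= %d to cover the 2 ms window", need))
  if (length(msg)) msg else TRUE
})

#' Ground truth of a synthetic scan
#'
#' Per stimulating electrode: the true bundle-threshold grid index and
#' amplitude, the axon-path orientation, the electrodes lying on the path,
#' and the activation model (per-amplitude activation probabilities plus
#' the per-repeat coupling uniforms) from which per-trial activation
#' outcomes are derived.
#'
#' @slot electrode integer stimulating electrodes.
#' @slot thresholdIndex,thresholdAmplitude true threshold per electrode.
#' @slot orientation axon-path orientation in radians.
#' @slot pathElectrodes list of integer vectors: electrodes on each path.
#' @slot activationProb matrix (stim x amplitude) of activation
#'   probabilities.
#' @slot couplingU matrix (stim x repeat) of the shared uniform draws; the
#'   trial at amplitude index a is active iff U <= activationProb[, a],
#'   which makes activation non-decreasing in amplitude within a repeat.
#' @slot grid the [AmplitudeGrid-class].
#' @seealso [simulateScan()], [truthThresholds()], [activationOutcomes()].
#' @export
setClass("GroundTruth",
  representation(
    electrode = "integer",
    thresholdIndex = "integer",
    thresholdAmplitude = "numeric",
    orientation = "numeric",
    pathElectrodes = "list",
    activationProb = "matrix",
    couplingU = "matrix",
    grid = "AmplitudeGrid"
  )
)

setValidity("GroundTruth", function(object) {
  n <- length(object@electrode)
  if (length(object@thresholdIndex) != n || length(object@orientation) != n ||
      length(object@pathElectrodes) != n)
    return("per-electrode slots must have equal length")
  nAmp <- length(object@grid@amplitudes)
  if (any(object@thresholdIndex < 1L | object@thresholdIndex > nAmp, na.rm = TRUE))
    return("ground-truth thresholds must be on the amplitude grid")
  p <- object@activationProb
  if (any(p < 0 | p > 1)) return("activation probabilities must lie in [0, 1]")
  if (nrow(p) && any(apply(p, 1L, function(x) any(diff(x) < -1e-12))))
    return("activation probability must be non-decreasing in amplitude")
  TRUE
})

#' Agreement between two threshold sets
#'
#' Summary of the agreement between detected and reference bundle
#' thresholds over the electrodes detected in both sets: the fraction
#' within one amplitude-grid step (equivalent to +/-10% on a 10% geometric
#' grid), the exact-match fraction, and the Pearson correlation of the
#' threshold amplitudes. Electrodes lacking a threshold in either set are
#' excluded from the comparison and counted separately.
#'
#' @slot nCompared electrodes with a threshold in both sets.
#' @slot fractionWithinOneStep,fractionExact agreement fractions (NA when
#'   nCompared is 0).
#' @slot pearsonR correlation of threshold amplitudes (NA when fewer than
#'   2 electrodes are jointly detected or a set is constant).
#' @slot nDetectedOnly,nReferenceOnly,nNeither exclusion counts.
#' @seealso [compareThresholds()].
#' @export
setClass("AgreementReport",
  representation(
    nCompared = "integer",
    fractionWithinOneStep = "numeric",
    fractionExact = "numeric",
    pearsonR = "numeric",
    nDetectedOnly = "integer",
    nReferenceOnly = "integer",
    nNeither = "integer"
  )
)

setValidity("AgreementReport", function(object) {
  f1 <- object@fractionWithinOneStep
  f0 <- object@fractionExact
  if (!is.na(f1) && (f1 < 0 || f1 > 1)) return("fractions must lie in [0, 1]")
  if (!is.na(f0) && (f0 < 0 || f0 > 1)) return("fractions must lie in [0, 1]")
  if (!is.na(f0) && !is.na(f1) && f0 > f1 + 1e-12)
    return("fractionExact cannot exceed fractionWithinOneStep")
  TRUE
})
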