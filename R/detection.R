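#' Bundle-activation detection
#'
#' The detection pipeline estimates, independently for every stimulating
#' electrode, the lowest stimulation amplitude that evokes bidirectional
#' axonal activity. It proceeds in five steps: (1) subtract the electrical
#' stimulation artifact, estimated as the repeat-mean recording at the
#' lowest amplitude; (2) extract per-trial spike times as the within-window
#' argmin of each trace (extracellular spikes have negative peaks); (3)
#' keep recording electrodes whose across-repeat spike-time variance falls
#' below a chi-squared cutoff derived from a uniform-timing null; (4)
#' prune each amplitude's signal electrodes to those also flagged at every
#' higher amplitude (evoked responses are monotone in amplitude); (5)
#' report the lowest amplitude whose pruned set touches at least two
#' distinct borders of the rectangular array.
#'
#' @name detection
NULL

# column variances with denominator n-1, matching the chi-squared scaling
.colVars <- function(m) {
  n <- nrow(m)
  cm <- colMeans(m)
  (colSums(m * m) - n * cm * cm) / (n - 1)
}

#' Subtract the electrical stimulation artifact
#'
#' Estimates the artifact for one stimulating electrode as the mean over
#' repeats of the recording at the lowest grid amplitude, and subtracts it
#' from every trace at every higher amplitude. The estimate is not scaled
#' with stimulation amplitude. Any repeat-independent signal applied
#' identically at all amplitudes cancels exactly.
#'
#' @param scan a [ScanRecording-class].
#' @param es stimulating electrode index (must be among
#'   `stimElectrodes(scan)`).
#' @return numeric array with dims (amplitude, repeat, recording
#'   electrode, sample) covering the amplitudes strictly above the lowest;
#'   attribute `ampIndices` gives their grid indices.
#' @export
subtractArtifact <- function(scan, es) {
  i <- match(as.integer(es), scan@stimElectrodes)
  if (is.na(i)) stop("electrode ", es, " was not stimulated in this scan")
  d <- dim(scan@voltages)
  block <- array(scan@voltages[i, , , , ], d[-1L])  # (A, R, E, T)
  .subtractArtifactBlock(block)
}

# block: (A, R, E, T) raw voltages for one stimulating electrode
.subtractArtifactBlock <- function(block) {
  d <- dim(block)
  A <- d[1L]
  if (A < 2L) stop("need at least 2 amplitudes (the lowest is the artifact reference)")
  ref <- colMeans(array(block[1L, , , ], d[-1L]))   # (E, T) mean over repeats
  v <- block[-1L, , , , drop = FALSE]               # (A-1, R, E, T)
  # recycle the (E, T) artifact across the leading (amplitude, repeat) axes
  dv <- dim(v)
  v <- v - rep(ref, each = dv[1L] * dv[2L])
  dim(v) <- dv
  structure(v, ampIndices = 2L:A)
}

#' Extract per-trial spike times
#'
#' For every (amplitude, repeat, recording electrode), the spike time is
#' the sample index of the minimum artifact-corrected voltage within the
#' analysis window (the negative extracellular spike peak). Samples
#' outside the window are ignored; ties resolve to the earliest sample.
#'
#' @param block artifact-corrected array (amplitude, repeat, recording
#'   electrode, sample), e.g. from [subtractArtifact()].
#' @param window integer vector of 1-based sample indices, e.g. from
#'   [windowSamples()].
#' @return integer array (amplitude, repeat, recording electrode) of
#'   absolute sample indices; attribute `ampIndices` is carried over.
#' @export
extractSpikeTimes <- function(block, window) {
  d <- dim(block)
  if (length(d) != 4L) stop("block must be a 4-D (amplitude, repeat, electrode, sample) array")
  window <- as.integer(window)
  if (length(window) == 0L) stop("empty analysis window")
  if (any(window < 1L) || any(window > d[4L]))
    stop("analysis window outside the recorded samples")
  m <- block[, , , window, drop = FALSE]
  dim(m) <- c(d[1L] * d[2L] * d[3L], length(window))
  rel <- max.col(-m, ties.method = "first")
  t <- array(window[rel], d[1:3])
  structure(t, ampIndices = attr(block, "ampIndices"))
}

#' Spike-time variance cutoff under the uniform-timing null
#'
#' Under the null hypothesis that spike times are uniform over the `m`
#' window samples, the sample variance of `n` repeats (denominator n-1)
#' satisfies \eqn{(n-1) s^2 / \sigma_0^2 \sim \chi^2_{n-1}} with
#' \eqn{\sigma_0^2 = (m^2 - 1)/12}, the variance of a discrete uniform
#' variable. The cutoff is the `pValue` quantile of that null:
#' \eqn{c = \sigma_0^2\, Q_{\chi^2_{n-1}}(p) / (n-1)}. Electrodes whose
#' spike-time variance falls strictly below `c` are flagged as carrying
#' evoked activity. The discrete uniform is platykurtic relative to the
#' chi-squared approximation, so the realized false-flag rate is below
#' the nominal level.
#'
#' @param nRepeats number of repeats n (>= 2).
#' @param windowLength number of window samples m (>= 2).
#' @param pValue test level in (0, 1).
#' @return the variance cutoff in samples^2.
#' @examples
#' varianceCutoff(25, 35, 0.05)  # ~58.9 samples^2
#' @export
varianceCutoff <- function(nRepeats, windowLength, pValue) {
  if (nRepeats < 2L) stop("nRepeats must be >= 2")
  if (windowLength < 2L) stop("windowLength must be >= 2")
  if (!(pValue > 0 && pValue < 1)) stop("pValue must be in (0, 1)")
  sigma0sq <- (windowLength^2 - 1) / 12
  sigma0sq * stats::qchisq(pValue, df = nRepeats - 1L) / (nRepeats - 1L)
}

#' Extract signal electrodes at one amplitude
#'
#' Flags the recording electrodes whose spike-time variance across repeats
#' (denominator n-1) is strictly below the cutoff; electrodes listed in
#' `exclude` are never flagged.
#'
#' @param times integer matrix (repeat x recording electrode) of spike
#'   times at one amplitude.
#' @param cutoff variance cutoff from [varianceCutoff()].
#' @param exclude recording electrodes to exclude.
#' @return sorted integer vector of flagged electrode indices.
#' @export
extractSignalElectrodes <- function(times, cutoff, exclude = integer(0)) {
  if (!is.matrix(times)) stop("times must be a (repeat x electrode) matrix")
  if (nrow(times) < 2L) stop("need at least 2 repeats to compute a variance")
  v <- .colVars(times)
  flagged <- which(v < cutoff)
  sort(setdiff(flagged, as.integer(exclude)))
}

#' Prune signal electrodes across amplitudes
#'
#' The activated set at each amplitude is the intersection of the signal
#' sets at that amplitude and all higher amplitudes, computed iteratively
#' from the highest amplitude down. The result is nested: the activated
#' set can only grow with amplitude.
#'
#' @param signal list of integer vectors of signal electrodes, ordered
#'   from lowest to highest amplitude.
#' @return list of integer vectors (activated sets), same order.
#' @examples
#' pruneSignalElectrodes(list(c(1, 2), c(2, 3), c(2, 3, 4)))
#' @export
pruneSignalElectrodes <- function(signal) {
  A <- length(signal)
  if (A == 0L) return(list())
  activated <- vector("list", A)
  activated[[A]] <- sort(as.integer(signal[[A]]))
  if (A > 1L) for (j in (A - 1L):1L)
    activated[[j]] <- sort(intersect(as.integer(signal[[j]]), activated[[j + 1L]]))
  activated
}

#' Determine the bundle-activation threshold from activated sets
#'
#' Returns the lowest grid amplitude whose activated electrode set touches
#' at least `minBorders` distinct borders of the array, or `NA` if no
#' tested amplitude qualifies. Because the activated sets are nested, the
#' qualifying amplitudes form an upward-closed set and the first
#' qualifying amplitude is well defined.
#'
#' @param activated list of activated electrode sets, lowest to highest
#'   amplitude (from [pruneSignalElectrodes()]).
#' @param array the [ElectrodeArray-class].
#' @param grid the [AmplitudeGrid-class].
#' @param ampIndices grid indices corresponding to the entries of
#'   `activated` (default: taken from the attribute set by the upstream
#'   steps, else `2:(length(activated)+1)`).
#' @param minBorders required number of distinct borders (default 2).
#' @param cornerRule `"literal"` or `"two-electrode"`; see
#'   [DetectionConfig()].
#' @return list with `index` (grid index or `NA`) and `amplitude` (uA or
#'   `NA`).
#' @export
detectBundleThreshold <- function(activated, array, grid,
                                  ampIndices = NULL, minBorders = 2L,
                                  cornerRule = c("literal", "two-electrode")) {
  cornerRule <- match.arg(cornerRule)
  if (is.null(ampIndices)) {
    ampIndices <- attr(activated, "ampIndices")
    if (is.null(ampIndices)) ampIndices <- seq_along(activated) + 1L
  }
  stopifnot(length(ampIndices) == length(activated))
  for (j in seq_along(activated)) {
    if (.meetsBorderRule(activated[[j]], array, minBorders, cornerRule)) {
      idx <- as.integer(ampIndices[j])
      return(list(index = idx, amplitude = grid@amplitudes[idx]))
    }
  }
  list(index = NA_integer_, amplitude = NA_real_)
}

# Vectorized steps 3-5 on a spike-time array for one stimulating
# electrode. times: (A', R, E) integer array; repeats: optional subset of
# the repeat axis. Returns the grid index of the threshold or NA.
.detectFromTimes <- function(times, ampIndices, array, grid, config,
                             windowLength, repeats = NULL) {
  if (!is.null(repeats)) times <- times[, repeats, , drop = FALSE]
  d <- dim(times)
  n <- d[2L]
  cutoff <- varianceCutoff(n, windowLength, config@pValue)
  tm <- aperm(times, c(2L, 1L, 3L))
  dim(tm) <- c(n, d[1L] * d[3L])
  v <- matrix(.colVars(tm), d[1L], d[3L])            # (A', E)
  signal <- v < cutoff
  if (length(config@excludeRecording))
    signal[, config@excludeRecording] <- FALSE
  # reverse cumulative AND across amplitudes = monotone pruning
  act <- signal
  if (d[1L] > 1L) for (j in (d[1L] - 1L):1L)
    act[j, ] <- act[j, ] & act[j + 1L, ]
  borderMat <- matrix(FALSE, d[3L], 4L)
  for (b in seq_along(array@borderSets))
    borderMat[array@borderSets[[b]], b] <- TRUE
  counts <- rowSums((act %*% borderMat) > 0)
  cand <- which(counts >= config@minBorders)
  if (!length(cand)) return(NA_integer_)
  if (config@cornerRule == "literal") return(as.integer(ampIndices[cand[1L]]))
  for (j in cand) {
    if (.meetsBorderRule(which(act[j, ]), array, config@minBorders, "two-electrode"))
      return(as.integer(ampIndices[j]))
  }
  NA_integer_
}

# steps 1-2 for one raw block: (A, R, E, T) -> spike-time array (A-1, R, E)
.blockSpikeTimes <- function(block, config, samplingRate) {
  v <- .subtractArtifactBlock(block)
  extractSpikeTimes(v, windowSamples(config, samplingRate))
}

#' Run bundle detection on a scan
#'
#' Applies the five detection steps independently to every stimulating
#' electrode of the scan. The lowest grid amplitude serves as the artifact
#' reference and is excluded from the candidate thresholds. The result is
#' deterministic given the input, and invariant under permutation of the
#' repeat axis, uniform positive rescaling of the voltages, and any
#' repeat-independent additive signal applied identically at all
#' amplitudes.
#'
#' @param scan a [ScanRecording-class].
#' @param config a [DetectionConfig-class].
#' @return a [BundleThresholds-class] with one entry per stimulating
#'   electrode.
#' @export
runDetection <- function(scan, config = DetectionConfig()) {
  stopifnot(is(scan, "ScanRecording"), is(config, "DetectionConfig"))
  validObject(scan); validObject(config)
  if (nRepeats(scan) < 2L) stop("detection needs at least 2 repeats")
  win <- windowSamples(config, scan@samplingRate)
  d <- dim(scan@voltages)
  idx <- integer(d[1L])
  for (i in seq_len(d[1L])) {
    block <- array(scan@voltages[i, , , , ], d[-1L])
    times <- tryCatch(.blockSpikeTimes(block, config, scan@samplingRate),
                      error = function(e) stop("stimulating electrode ",
                                               scan@stimElectrodes[i], ": ",
                                               conditionMessage(e)))
    idx[i] <- .detectFromTimes(times, attr(times, "ampIndices"),
                               scan@array, scan@grid, config, length(win))
  }
  BundleThresholds(scan@stimElectrodes, idx, scan@grid)
}
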