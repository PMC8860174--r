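#' Construct a detection configuration
#'
#' @param pValue level of the spike-time variance test (default 0.05, the
#'   pipeline's only model hyperparameter).
#' @param windowStartMs,windowEndMs spike-time analysis window in ms after
#'   the stimulus (defaults 0.3 and 2; the early blank avoids the residual
#'   stimulation artifact).
#' @param minBorders distinct borders the activated set must touch
#'   (default 2, the signature of bidirectional axonal propagation).
#' @param excludeRecording recording electrodes to exclude from signal
#'   sets (default none; the stimulating electrode's own recording is kept).
#' @param cornerRule `"literal"` (default: a lone corner electrode lies on
#'   two borders and satisfies the rule alone) or `"two-electrode"`
#'   (distinct electrodes required on distinct borders).
#' @return a [DetectionConfig-class].
#' @export
DetectionConfig <- function(pValue = 0.05, windowStartMs = 0.3, windowEndMs = 2,
                            minBorders = 2L, excludeRecording = integer(0),
                            cornerRule = c("literal", "two-electrode")) {
  new("DetectionConfig",
      pValue = as.numeric(pValue),
      windowStartMs = as.numeric(windowStartMs),
      windowEndMs = as.numeric(windowEndMs),
      minBorders = as.integer(minBorders),
      excludeRecording = as.integer(excludeRecording),
      cornerRule = match.arg(cornerRule))
}

setMethod("show", "DetectionConfig", function(object) {
  cat(sprintf(paste0("DetectionConfig: p = %g, window %g-%g ms, ",
                     ">= %d borders (%s corner rule), %d excluded electrodes\n"),
              object@pValue, object@windowStartMs, object@windowEndMs,
              object@minBorders, object@cornerRule,
              length(object@excludeRecording)))
})

#' Analysis-window samples for a sampling rate
#'
#' Discretizes the analysis window onto the sample grid: 1-based sample
#' indices from \eqn{\lceil t_0 f_s \rceil} to \eqn{\lfloor t_1 f_s
#' \rfloor} inclusive (sample 1 being the moment of stimulation). At 20
#' kHz the default 0.3-2 ms window maps to samples 7..41, m = 35 samples.
#'
#' @param config a [DetectionConfig-class].
#' @param samplingRate sampling rate in Hz.
#' @return integer vector of sample indices.
#' @export
windowSamples <- function(config, samplingRate) {
  lo <- ceiling(config@windowStartMs * 1e-3 * samplingRate) + 1L
  hi <- floor(config@windowEndMs * 1e-3 * samplingRate) + 1L
  if (hi < lo) stop("empty analysis window at this sampling rate")
  as.integer(lo):as.integer(hi)
}
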