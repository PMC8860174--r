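#' Construct a ScanRecording
#'
#' @param voltages 5-D numeric array, dims (stimulating electrode,
#'   amplitude, repeat, recording electrode, time sample), in uV. The
#'   stimulus occurs at the first time sample.
#' @param samplingRate sampling rate in Hz (default 20000).
#' @param grid the [AmplitudeGrid-class] of the amplitude axis.
#' @param array the [ElectrodeArray-class] of the recording axis.
#' @param stimElectrodes electrode indices of the first axis (default:
#'   the first `dim(voltages)[1]` electrodes).
#' @return a [ScanRecording-class].
#' @export
ScanRecording <- function(voltages, samplingRate = 20000, grid, array,
                          stimElectrodes = seq_len(dim(voltages)[1L])) {
  new("ScanRecording", voltages = voltages,
      samplingRate = as.numeric(samplingRate),
      stimElectrodes = as.integer(stimElectrodes),
      grid = grid, array = array)
}

#' Accessors for ScanRecording
#'
#' @param x a [ScanRecording-class].
#' @name ScanRecording-accessors
NULL

#' @rdname ScanRecording-accessors
#' @export
setMethod("voltages", "ScanRecording", function(x) x@voltages)
#' @rdname ScanRecording-accessors
#' @export
setMethod("samplingRate", "ScanRecording", function(x) x@samplingRate)
#' @rdname ScanRecording-accessors
#' @export
setMethod("stimElectrodes", "ScanRecording", function(x) x@stimElectrodes)
#' @rdname ScanRecording-accessors
#' @export
setMethod("amplitudeGrid", "ScanRecording", function(x) x@grid)
#' @rdname ScanRecording-accessors
#' @export
setMethod("electrodeArray", "ScanRecording", function(x) x@array)
#' @rdname ScanRecording-accessors
#' @export
setMethod("nRepeats", "ScanRecording", function(x) dim(x@voltages)[3L])

setMethod("show", "ScanRecording", function(object) {
  d <- dim(object@voltages)
  cat(sprintf(paste0("ScanRecording: %d stim electrodes x %d amplitudes x ",
                     "%d repeats x %d recording electrodes x %d samples @ %g kHz\n"),
              d[1L], d[2L], d[3L], d[4L], d[5L], object@samplingRate / 1000))
})
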