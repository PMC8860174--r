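#' @rdname ElectrodeArray-accessors
#' @export
setGeneric("nRows", function(x) standardGeneric("nRows"))

#' @rdname ElectrodeArray-accessors
#' @export
setGeneric("nCols", function(x) standardGeneric("nCols"))

#' @rdname ElectrodeArray-accessors
#' @export
setGeneric("pitch", function(x) standardGeneric("pitch"))

#' @rdname ElectrodeArray-accessors
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' @rdname ElectrodeArray-accessors
#' @export
setGeneric("borderSets", function(x) standardGeneric("borderSets"))

#' @rdname ElectrodeArray-accessors
#' @export
setGeneric("nElectrodes", function(x) standardGeneric("nElectrodes"))

#' @rdname AmplitudeGrid
#' @export
setGeneric("amplitudes", function(x) standardGeneric("amplitudes"))

#' @rdname ScanRecording-accessors
#' @export
setGeneric("voltages", function(x) standardGeneric("voltages"))

#' @rdname ScanRecording-accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname ScanRecording-accessors
#' @export
setGeneric("stimElectrodes", function(x) standardGeneric("stimElectrodes"))

#' @rdname ScanRecording-accessors
#' @export
setGeneric("amplitudeGrid", function(x) standardGeneric("amplitudeGrid"))

#' @rdname ScanRecording-accessors
#' @export
setGeneric("electrodeArray", function(x) standardGeneric("electrodeArray"))

#' @rdname ScanRecording-accessors
#' @export
setGeneric("nRepeats", function(x) standardGeneric("nRepeats"))

#' @rdname BundleThresholds-accessors
#' @export
setGeneric("thresholdIndices", function(x) standardGeneric("thresholdIndices"))

#' @rdname BundleThresholds-accessors
#' @export
setGeneric("thresholdAmplitudes", function(x) standardGeneric("thresholdAmplitudes"))

#' @rdname BundleThresholds-accessors
#' @export
setGeneric("isDetected", function(x) standardGeneric("isDetected"))

#' @rdname GroundTruth-accessors
#' @export
setGeneric("truthThresholds", function(x) standardGeneric("truthThresholds"))

#' @rdname GroundTruth-accessors
#' @export
setGeneric("activationOutcomes", function(x, electrode) standardGeneric("activationOutcomes"))
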