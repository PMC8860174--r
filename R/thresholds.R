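#' Construct a BundleThresholds object
#'
#' @param electrode integer stimulating-electrode indices.
#' @param index integer grid indices of the detected thresholds, `NA` for
#'   electrodes where no tested amplitude met the border rule.
#' @param grid the [AmplitudeGrid-class] the indices refer to.
#' @return a [BundleThresholds-class].
#' @export
BundleThresholds <- function(electrode, index, grid) {
  electrode <- as.integer(electrode)
  index <- as.integer(index)
  amp <- rep(NA_real_, length(index))
  det <- !is.na(index)
  amp[det] <- grid@amplitudes[index[det]]
  new("BundleThresholds", electrode = electrode, index = index,
      amplitude = amp, grid = grid)
}

#' Accessors for BundleThresholds
#'
#' @param x a [BundleThresholds-class].
#' @return `thresholdIndices`: integer grid indices (NA = not found);
#'   `thresholdAmplitudes`: amplitudes in uA (NA = not found);
#'   `isDetected`: logical vector.
#' @name BundleThresholds-accessors
NULL

#' @rdname BundleThresholds-accessors
#' @export
setMethod("thresholdIndices", "BundleThresholds", function(x) {
  stats::setNames(x@index, x@electrode)
})

#' @rdname BundleThresholds-accessors
#' @export
setMethod("thresholdAmplitudes", "BundleThresholds", function(x) {
  stats::setNames(x@amplitude, x@electrode)
})

#' @rdname BundleThresholds-accessors
#' @export
setMethod("isDetected", "BundleThresholds", function(x) !is.na(x@index))

#' @export
setMethod("length", "BundleThresholds", function(x) length(x@electrode))

setMethod("show", "BundleThresholds", function(object) {
  det <- sum(!is.na(object@index))
  cat(sprintf("BundleThresholds: %d stimulating electrodes, %d detected, %d not found\n",
              length(object@electrode), det, length(object@electrode) - det))
  if (det) {
    a <- object@amplitude[!is.na(object@amplitude)]
    cat(sprintf("  detected thresholds: %.3g - %.3g uA (median %.3g)\n",
                min(a), max(a), stats::median(a)))
  }
})

#' @rdname BundleThresholds-accessors
#' @param row.names,optional,... passed on conventionally (unused).
#' @method as.data.frame BundleThresholds
#' @export
as.data.frame.BundleThresholds <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(
    stim_electrode = x@electrode,
    threshold_uA = x@amplitude,
    threshold_index = x@index,
    status = ifelse(is.na(x@index), "not_found", "detected"),
    stringsAsFactors = FALSE
  )
}
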