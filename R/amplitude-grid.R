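#' Construct an amplitude grid
#'
#' @param amplitudes strictly increasing positive amplitudes in uA.
#' @return an [AmplitudeGrid-class].
#' @rdname AmplitudeGrid
#' @export
AmplitudeGrid <- function(amplitudes) {
  new("AmplitudeGrid", amplitudes = as.numeric(amplitudes))
}

#' Standard geometric stimulation amplitude grid
#'
#' The standard single-electrode scan grid: `nLevels` current levels
#' starting at `aMin` uA, each 10% above the previous
#' (\eqn{a_k = a_{min}\,\mathrm{ratio}^{k-1}}). With the defaults the grid
#' spans 0.1 uA to \eqn{0.1 \cdot 1.1^{39} \approx 4.1} uA. One step on
#' this grid corresponds to a 10% amplitude change, which is why threshold
#' agreement within one grid step equals agreement within +/-10%.
#'
#' @param nLevels number of current levels (default 40).
#' @param aMin lowest amplitude in uA (default 0.1).
#' @param ratio geometric step (default 1.1).
#' @return an [AmplitudeGrid-class].
#' @examples
#' round(amplitudes(defaultAmplitudeGrid())[40], 1)  # 4.1 uA
#' @export
defaultAmplitudeGrid <- function(nLevels = 40, aMin = 0.1, ratio = 1.1) {
  AmplitudeGrid(aMin * ratio^(seq_len(nLevels) - 1))
}

#' @param x an [AmplitudeGrid-class].
#' @rdname AmplitudeGrid
#' @export
setMethod("amplitudes", "AmplitudeGrid", function(x) x@amplitudes)

#' @export
setMethod("length", "AmplitudeGrid", function(x) length(x@amplitudes))

setMethod("show", "AmplitudeGrid", function(object) {
  a <- object@amplitudes
  cat(sprintf("AmplitudeGrid: %d levels, %.4g - %.4g uA\n",
              length(a), a[1L], a[length(a)]))
})
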