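#' Construct a rectangular electrode array
#'
#' Builds the geometry of a rectangular multi-electrode array: electrode
#' coordinates on a regular grid and the four border sets (first/last row,
#' first/last column). Electrodes are numbered 1-based in row-major order
#' from the top-left corner, so electrode \eqn{(r, c)} has index
#' \eqn{(r-1) n_{cols} + c}, position \eqn{x = (c-1)\,\mathrm{pitch}},
#' \eqn{y = (r-1)\,\mathrm{pitch}}.
#'
#' A corner electrode belongs to exactly two border sets, a non-corner edge
#' electrode to one, and an interior electrode to none.
#'
#' @param nRows,nCols grid dimensions, each at least 2.
#' @param pitch inter-electrode spacing in micrometres (default 60).
#' @return an [ElectrodeArray-class].
#' @examples
#' arr <- ElectrodeArray(16, 32)       # 512-electrode array
#' lengths(borderSets(arr))
#' @export
ElectrodeArray <- function(nRows, nCols, pitch = 60) {
  nRows <- as.integer(nRows)
  nCols <- as.integer(nCols)
  if (is.na(nRows) || is.na(nCols) || nRows < 2L || nCols < 2L)
    stop("nRows and nCols must both be >= 2")
  row <- rep(seq_len(nRows), each = nCols)
  col <- rep(seq_len(nCols), times = nRows)
  pos <- cbind(x = (col - 1) * pitch, y = (row - 1) * pitch)
  idx <- seq_len(nRows * nCols)
  borders <- list(
    left   = idx[col == 1L],
    right  = idx[col == nCols],
    top    = idx[row == 1L],
    bottom = idx[row == nRows]
  )
  new("ElectrodeArray", nRows = nRows, nCols = nCols, pitch = as.numeric(pitch),
      positions = pos, borderSets = borders)
}

#' Accessors for ElectrodeArray
#'
#' @param x an [ElectrodeArray-class].
#' @return `nRows`, `nCols`, `nElectrodes` return integers; `pitch` a
#'   number; `positions` an (electrodes x 2) coordinate matrix in um;
#'   `borderSets` the named list of four border index vectors.
#' @name ElectrodeArray-accessors
NULL

#' @rdname ElectrodeArray-accessors
#' @export
setMethod("nRows", "ElectrodeArray", function(x) x@nRows)
#' @rdname ElectrodeArray-accessors
#' @export
setMethod("nCols", "ElectrodeArray", function(x) x@nCols)
#' @rdname ElectrodeArray-accessors
#' @export
setMethod("pitch", "ElectrodeArray", function(x) x@pitch)
#' @rdname ElectrodeArray-accessors
#' @export
setMethod("positions", "ElectrodeArray", function(x) x@positions)
#' @rdname ElectrodeArray-accessors
#' @export
setMethod("borderSets", "ElectrodeArray", function(x) x@borderSets)
#' @rdname ElectrodeArray-accessors
#' @export
setMethod("nElectrodes", "ElectrodeArray", function(x) x@nRows * x@nCols)

setMethod("show", "ElectrodeArray", function(object) {
  cat(sprintf("ElectrodeArray: %d x %d (%d electrodes), pitch %g um\n",
              object@nRows, object@nCols, nElectrodes(object), object@pitch))
})

.checkElectrodeIndices <- function(electrodes, array) {
  if (length(electrodes) == 0L) return(integer(0))
  electrodes <- as.integer(electrodes)
  bad <- electrodes[is.na(electrodes) | electrodes < 1L |
                    electrodes > nElectrodes(array)]
  if (length(bad))
    stop("invalid electrode index: ", paste(bad, collapse = ", "))
  electrodes
}

#' Count distinct array borders touched by a set of electrodes
#'
#' Returns the number of the four border sets (left, right, top, bottom)
#' that have a non-empty intersection with the given electrode set. A
#' single corner electrode touches two borders. The count is monotone
#' under set inclusion.
#'
#' @param electrodes integer vector of electrode indices (may be empty).
#' @param array an [ElectrodeArray-class].
#' @return integer in 0..4.
#' @examples
#' arr <- ElectrodeArray(3, 3)
#' bordersTouched(1, arr)        # corner: 2
#' bordersTouched(5, arr)        # interior: 0
#' @export
bordersTouched <- function(electrodes, array) {
  electrodes <- .checkElectrodeIndices(electrodes, array)
  sum(vapply(array@borderSets, function(b) any(electrodes %in% b), logical(1L)))
}

# Does the electrode set satisfy the border rule? Under "literal", a lone
# corner counts as two borders. Under "two-electrode", minBorders distinct
# electrodes on distinct borders are required, i.e. the electrode/border
# bipartite graph must admit a matching of size minBorders (checked by
# Hall's condition over the <= 2^4 border subsets).
.meetsBorderRule <- function(electrodes, array, minBorders = 2L,
                             cornerRule = c("literal", "two-electrode")) {
  cornerRule <- match.arg(cornerRule)
  electrodes <- .checkElectrodeIndices(electrodes, array)
  touched <- vapply(array@borderSets, function(b) any(electrodes %in% b), logical(1L))
  if (sum(touched) < minBorders) return(FALSE)
  if (cornerRule == "literal") return(TRUE)
  borderIdx <- which(touched)
  onBorder <- lapply(array@borderSets[borderIdx],
                     function(b) electrodes[electrodes %in% b])
  # max bipartite matching size >= minBorders iff some minBorders-subset S of
  # borders satisfies Hall's condition: every T subseteq S has |N(T)| >= |T|
  subsetsOf <- function(v, k) if (k == 0L) list(integer(0)) else utils::combn(v, k, simplify = FALSE)
  for (S in subsetsOf(seq_along(borderIdx), min(minBorders, length(borderIdx)))) {
    if (length(S) < minBorders) next
    hall <- TRUE
    for (k in seq_along(S)) {
      for (Tsub in subsetsOf(S, k)) {
        if (length(unique(unlist(onBorder[Tsub]))) < length(Tsub)) { hall <- FALSE; break }
      }
      if (!hall) break
    }
    if (hall) return(TRUE)
  }
  FALSE
}
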