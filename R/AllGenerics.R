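#' @rdname TagSet-class
#' @param x an object.
#' @export
setGeneric("stageId", function(x) standardGeneric("stageId"))

#' @rdname TagSet-class
#' @export
setGeneric("replicateId", function(x) standardGeneric("replicateId"))

#' @rdname TagSet-class
#' @export
setGeneric("tagPositions", function(x) standardGeneric("tagPositions"))

#' @rdname TagSet-class
#' @export
setGeneric("nTags", function(x) standardGeneric("nTags"))

#' @rdname DensityTrack-class
#' @param x an object.
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' @rdname DensityTrack-class
#' @export
setGeneric("windowSize", function(x) standardGeneric("windowSize"))

#' @rdname DensityTrack-class
#' @export
setGeneric("trackScores", function(x) standardGeneric("trackScores"))

#' Compute the binned sliding-window cleavage density of a TagSet
#'
#' @param tags a [TagSet].
#' @param binSize bin width in bp; default 20.
#' @param window smoothing window in bp centred on each bin midpoint; default
#'   150. Must be at least `binSize`.
#' @return a [DensityTrack].
#' @details Each bin's score is the number of tags `t` with
#'   `mid - window/2 <= t < mid + window/2` where `mid` is the bin midpoint
#'   (0-based). With the 20/150 defaults every tag contributes to exactly 7 or
#'   8 bins depending on its alignment to the bin grid.
#' @export
setGeneric("binDensity", function(tags, binSize = 20L, window = 150L)
  standardGeneric("binDensity"))
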