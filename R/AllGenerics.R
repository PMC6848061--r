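#' Accessors for movie containers and result objects
#'
#' \code{frames} returns the frame x row x col array; \code{geometry} the
#' \code{AcquisitionGeometry}; \code{stackKind} the stack kind;
#' \code{provenance} the ordered record of preprocessing steps;
#' \code{landmarks} the \code{LandmarkFrame}; \code{peakAmplitude} the
#' detected peak fractional dF/F; \code{overlapCounts} and
#' \code{majorityMask} the grids of an \code{OverlapMap}.
#'
#' @param x an object
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @rdname accessors
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))
#' @rdname accessors
#' @export
setGeneric("stackKind", function(x) standardGeneric("stackKind"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setGeneric("landmarks", function(x) standardGeneric("landmarks"))
#' @rdname accessors
#' @export
setGeneric("peakAmplitude", function(x) standardGeneric("peakAmplitude"))
#' @rdname accessors
#' @export
setGeneric("overlapCounts", function(x) standardGeneric("overlapCounts"))
#' @rdname accessors
#' @export
setGeneric("majorityMask", function(x) standardGeneric("majorityMask"))

#' @rdname accessors
#' @export
setMethod("frames", "TrialStack", function(x) x@frames)
#' @rdname accessors
#' @export
setMethod("frames", "DffMovie", function(x) x@frames)
#' @rdname accessors
#' @export
setMethod("geometry", "TrialStack", function(x) x@geometry)
#' @rdname accessors
#' @export
setMethod("geometry", "DffMovie", function(x) x@geometry)
#' @rdname accessors
#' @export
setMethod("stackKind", "TrialStack", function(x) x@kind)
#' @rdname accessors
#' @export
setMethod("provenance", "TrialStack", function(x) x@provenance)
#' @rdname accessors
#' @export
setMethod("provenance", "DffMovie", function(x) x@provenance)
#' @rdname accessors
#' @export
setMethod("landmarks", "TrialStack", function(x) x@landmarks)
#' @rdname accessors
#' @export
setMethod("peakAmplitude", "ResponseMetrics", function(x) x@peakAmplitude)
#' @rdname accessors
#' @export
setMethod("overlapCounts", "OverlapMap", function(x) x@counts)
#' @rdname accessors
#' @export
setMethod("majorityMask", "OverlapMap", function(x) x@contourMask)
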