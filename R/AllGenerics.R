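#' @include AllClasses.R
NULL

#' Accessors for curves, schedules, segment models and fit results
#'
#' Standard accessors: \code{curveTimes}, \code{curveValues} and
#' \code{frameDurations} read the slots of a [TimeCurve-class];
#' \code{frameDurations}, \code{frameStarts}, \code{frameMids},
#' \code{frameEnds} and \code{totalDuration} describe a
#' [FrameSchedule-class]; \code{territories} returns the segment-to-territory
#' map of a [SegmentModel-class]; \code{fittedParams}, \code{fittedMBF} and
#' \code{residualNorm} read kinetic fit results.
#'
#' @param x the object.
#' @return The corresponding slot or derived vector.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("curveTimes", function(x) standardGeneric("curveTimes"))
#' @rdname accessors
#' @export
setGeneric("curveValues", function(x) standardGeneric("curveValues"))
#' @rdname accessors
#' @export
setGeneric("frameDurations", function(x) standardGeneric("frameDurations"))
#' @rdname accessors
#' @export
setGeneric("frameStarts", function(x) standardGeneric("frameStarts"))
#' @rdname accessors
#' @export
setGeneric("frameMids", function(x) standardGeneric("frameMids"))
#' @rdname accessors
#' @export
setGeneric("frameEnds", function(x) standardGeneric("frameEnds"))
#' @rdname accessors
#' @export
setGeneric("totalDuration", function(x) standardGeneric("totalDuration"))
#' @rdname accessors
#' @export
setGeneric("territories", function(x) standardGeneric("territories"))
#' @rdname accessors
#' @export
setGeneric("fittedParams", function(x) standardGeneric("fittedParams"))
#' @rdname accessors
#' @export
setGeneric("fittedMBF", function(x) standardGeneric("fittedMBF"))
#' @rdname accessors
#' @export
setGeneric("residualNorm", function(x) standardGeneric("residualNorm"))

#' @rdname accessors
#' @export
setMethod("curveTimes", "TimeCurve", function(x) x@times)
#' @rdname accessors
#' @export
setMethod("curveValues", "TimeCurve", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("frameDurations", "TimeCurve", function(x) x@durations)

#' @rdname accessors
#' @export
setMethod("frameDurations", "FrameSchedule", function(x) x@durations)
#' @rdname accessors
#' @export
setMethod("frameStarts", "FrameSchedule",
          function(x) cumsum(c(0, x@durations[-length(x@durations)])))
#' @rdname accessors
#' @export
setMethod("frameMids", "FrameSchedule",
          function(x) frameStarts(x) + x@durations / 2)
#' @rdname accessors
#' @export
setMethod("frameEnds", "FrameSchedule", function(x) cumsum(x@durations))
#' @rdname accessors
#' @export
setMethod("totalDuration", "FrameSchedule", function(x) sum(x@durations))

#' @rdname accessors
#' @export
setMethod("territories", "SegmentModel", function(x) x@territories)

#' @rdname accessors
#' @export
setMethod("fittedParams", "PETFitResult", function(x) x@params)
#' @rdname accessors
#' @export
setMethod("fittedParams", "ToftsFitResult", function(x) x@params)
#' @rdname accessors
#' @export
setMethod("fittedMBF", "PETFitResult", function(x) x@mbf)
#' @rdname accessors
#' @export
setMethod("fittedMBF", "ToftsFitResult", function(x) x@mbf)
#' @rdname accessors
#' @export
setMethod("residualNorm", "PETFitResult", function(x) x@residualNorm)
#' @rdname accessors
#' @export
setMethod("residualNorm", "ToftsFitResult", function(x) x@residualNorm)

#' @rdname accessors
#' @export
setMethod("length", "TimeCurve", function(x) length(x@times))
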