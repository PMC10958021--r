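#' @name HomingTrack-generics
#' @title Accessor generics
#' @description Accessors for the S4 containers; user code should use these
#'   rather than reaching into slots.
#' @param x a [Track-class] or [SegmentationResult-class] object.
NULL

#' @rdname HomingTrack-generics
#' @return `eventId`: single character event identifier.
#' @export
setGeneric("eventId", function(x) standardGeneric("eventId"))

#' @rdname HomingTrack-generics
#' @return `animalId`: single character animal identifier.
#' @export
setGeneric("animalId", function(x) standardGeneric("animalId"))

#' @rdname HomingTrack-generics
#' @return `coords`: numeric matrix of fix positions.
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname HomingTrack-generics
#' @return `fixTimes`: POSIXct fix timestamps (UTC).
#' @export
setGeneric("fixTimes", function(x) standardGeneric("fixTimes"))

#' @rdname HomingTrack-generics
#' @return `coordFrame`: `"geographic"` or `"planar"`.
#' @export
setGeneric("coordFrame", function(x) standardGeneric("coordFrame"))

#' @rdname HomingTrack-generics
#' @return `nFixes`: integer number of fixes.
#' @export
setGeneric("nFixes", function(x) standardGeneric("nFixes"))

#' @rdname HomingTrack-generics
#' @return `chosenK`: integer number of segments selected.
#' @export
setGeneric("chosenK", function(x) standardGeneric("chosenK"))

#' @rdname HomingTrack-generics
#' @return `segmentBounds`: integer matrix of half-open `[start, end)`
#'   segment index intervals.
#' @export
setGeneric("segmentBounds", function(x) standardGeneric("segmentBounds"))

#' @rdname HomingTrack-generics
#' @return `contrastCurve`: data.frame with columns `K`, `J`, `D`.
#' @export
setGeneric("contrastCurve", function(x) standardGeneric("contrastCurve"))

#' @export
#' @rdname HomingTrack-generics
setMethod("eventId", "Track", function(x) x@eventId)

#' @export
#' @rdname HomingTrack-generics
setMethod("animalId", "Track", function(x) x@animalId)

#' @export
#' @rdname HomingTrack-generics
setMethod("coords", "Track", function(x) x@coords)

#' @export
#' @rdname HomingTrack-generics
setMethod("fixTimes", "Track", function(x) x@time)

#' @export
#' @rdname HomingTrack-generics
setMethod("coordFrame", "Track", function(x) x@frame)

#' @export
#' @rdname HomingTrack-generics
setMethod("nFixes", "Track", function(x) nrow(x@coords))

#' @export
#' @rdname HomingTrack-generics
setMethod("eventId", "SegmentationResult", function(x) x@eventId)

#' @export
#' @rdname HomingTrack-generics
setMethod("chosenK", "SegmentationResult", function(x) x@chosenK)

#' @export
#' @rdname HomingTrack-generics
setMethod("segmentBounds", "SegmentationResult", function(x) x@boundaries)

#' @export
#' @rdname HomingTrack-generics
setMethod("contrastCurve", "SegmentationResult", function(x) {
  data.frame(K = seq_along(x@Jcurve), J = x@Jcurve, D = x@Dcurve)
})

setMethod("show", "Track", function(object) {
  n <- nrow(object@coords)
  cat(sprintf("Track '%s' (animal '%s'): %d fixes, %s frame\n",
              object@eventId, object@animalId, n, object@frame))
  cat(sprintf("  from %s to %s (%.1f h)\n",
              format(object@time[1], tz = "UTC"), format(object@time[n], tz = "UTC"),
              as.numeric(difftime(object@time[n], object@time[1], units = "hours"))))
})

setMethod("show", "SegmentationResult", function(object) {
  cat(sprintf("SegmentationResult '%s': K = %d over %d steps\n",
              object@eventId, object@chosenK, length(object@series)))
  if (nrow(object@boundaries) > 0) {
    b <- object@boundaries
    cat("  segments:", paste(sprintf("[%d,%d)", b[, 1], b[, 2]), collapse = " "), "\n")
  }
  cat("  J(K):", paste(signif(object@Jcurve, 5), collapse = ", "), "\n")
})
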