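#' Track: time-ordered GPS fixes for one translocation event
#'
#' An S4 container for the post-release fixes of a single translocation
#' event. Coordinates are either geographic (lon, lat in WGS84 degrees) or
#' planar (x, y in meters); the frame is fixed per object and never mixed.
#' Timestamps are strictly increasing POSIXct in UTC.
#'
#' @slot eventId single character identifier of the translocation event.
#' @slot animalId single character identifier of the animal (animals
#'   translocated repeatedly share an `animalId` across events).
#' @slot coords numeric matrix with columns `c("lon","lat")` or `c("x","y")`,
#'   one row per fix.
#' @slot time `POSIXct` vector of fix timestamps (UTC), strictly increasing.
#' @slot frame `"geographic"` or `"planar"`.
#'
#' @seealso [Track()] constructor, [stepSeries()], [classifyHoming()]
#' @export
setClass("Track",
  representation(
    eventId  = "character",
    animalId = "character",
    coords   = "matrix",
    time     = "POSIXct",
    frame    = "character"
  )
)

setValidity("Track", function(object) {
  msgs <- character()
  if (length(object@eventId) != 1L) msgs <- c(msgs, "eventId must be length 1")
  if (length(object@animalId) != 1L) msgs <- c(msgs, "animalId must be length 1")
  if (!object@frame %in% c("geographic", "planar"))
    msgs <- c(msgs, "frame must be 'geographic' or 'planar'")
  n <- nrow(object@coords)
  if (is.null(n) || n < 2L) msgs <- c(msgs, "a Track needs at least 2 fixes")
  if (ncol(object@coords) != 2L) msgs <- c(msgs, "coords must have 2 columns")
  if (!is.numeric(object@coords) || anyNA(object@coords))
    msgs <- c(msgs, "coords must be numeric and non-missing")
  if (length(object@time) != nrow(object@coords))
    msgs <- c(msgs, "time and coords lengths differ")
  if (anyNA(object@time)) msgs <- c(msgs, "timestamps must be finite")
  if (length(object@time) > 1L && any(diff(as.numeric(object@time)) <= 0))
    msgs <- c(msgs, "timestamps must be strictly increasing (duplicates rejected)")
  if (identical(object@frame, "geographic") && nrow(object@coords) > 0) {
    if (any(abs(object@coords[, 2]) > 90)) msgs <- c(msgs, "latitude outside [-90, 90]")
    if (any(abs(object@coords[, 1]) > 180)) msgs <- c(msgs, "longitude outside [-180, 180]")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a Track
#'
#' @param eventId,animalId single character identifiers.
#' @param coords two-column numeric matrix of positions, one row per fix
#'   (lon/lat degrees for the geographic frame, x/y meters for planar).
#' @param time `POSIXct` timestamps (coerced to UTC), strictly increasing.
#' @param frame `"geographic"` or `"planar"`.
#' @return a [Track-class] object.
#' @examples
#' tr <- Track("e1", "a1",
#'   coords = cbind(x = c(0, 0, 100), y = c(0, 100, 100)),
#'   time = as.POSIXct("2020-03-01", tz = "UTC") + c(0, 1800, 3600),
#'   frame = "planar")
#' nFixes(tr)
#' @export
Track <- function(eventId, animalId, coords, time, frame = c("planar", "geographic")) {
  frame <- match.arg(frame)
  coords <- as.matrix(coords)
  dimnames(coords) <- list(NULL,
    if (frame == "geographic") c("lon", "lat") else c("x", "y"))
  storage.mode(coords) <- "double"
  attr(time, "tzone") <- "UTC"
  new("Track", eventId = as.character(eventId), animalId = as.character(animalId),
      coords = coords, time = time, frame = frame)
}

#' SegmentationResult: output of penalized-contrast trajectory segmentation
#'
#' Holds the chosen number of segments K, the segment boundaries over the
#' step series (half-open index intervals, contiguous and covering), the
#' optimal contrast curve J(K) and the normalized second-difference curve
#' D(K) used to choose K.
#'
#' @slot eventId event identifier (may be `NA` when segmenting a bare series).
#' @slot chosenK integer, the selected number of segments.
#' @slot boundaries integer matrix with columns `start`, `end`: half-open
#'   `[start, end)` 1-based index intervals over the segmented series.
#' @slot Jcurve numeric, minimal total contrast for K = 1..kmax.
#' @slot Dcurve numeric, normalized contrast second differences (NA at
#'   K = 1 and K = kmax where undefined).
#' @slot series the numeric series that was segmented.
#' @export
setClass("SegmentationResult",
  representation(
    eventId    = "character",
    chosenK    = "integer",
    boundaries = "matrix",
    Jcurve     = "numeric",
    Dcurve     = "numeric",
    series     = "numeric"
  )
)

setValidity("SegmentationResult", function(object) {
  msgs <- character()
  b <- object@boundaries
  if (nrow(b) != object@chosenK) msgs <- c(msgs, "boundary rows must equal chosenK")
  if (nrow(b) > 0) {
    if (b[1, 1] != 1L) msgs <- c(msgs, "segments must start at index 1")
    if (b[nrow(b), 2] != length(object@series) + 1L)
      msgs <- c(msgs, "segments must cover the series")
    if (nrow(b) > 1 && any(b[-1, 1] != b[-nrow(b), 2]))
      msgs <- c(msgs, "segments must be contiguous")
    if (any(b[, 2] <= b[, 1])) msgs <- c(msgs, "segments must be non-empty")
  }
  if (length(msgs)) msgs else TRUE
})
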