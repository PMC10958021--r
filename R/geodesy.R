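# Geodesic primitives. Geographic computations are spherical by default
# (haversine distance, initial great-circle azimuth) on R = 6371.0088 km:
# at translocation scales (<= 15 km) the difference from full ellipsoidal
# geodesy is far below GPS error. Planar frames are Euclidean with
# +y = north, +x = east.

EARTH_RADIUS_M <- 6371008.8

asPosMatrix <- function(p) {
  if (is.matrix(p)) p else matrix(as.numeric(p), ncol = 2)
}

#' Distance between two positions
#'
#' Euclidean distance in the planar frame; great-circle (haversine) distance
#' on a sphere of radius `radius` in the geographic frame. Vectorized over
#' rows when `a` and/or `b` are two-column matrices.
#'
#' @param a,b positions: length-2 numeric vectors `(x, y)` / `(lon, lat)`,
#'   or two-column matrices of such rows.
#' @param frame `"planar"` or `"geographic"`.
#' @param radius sphere radius in meters (geographic frame only).
#' @return distance(s) in meters.
#' @examples
#' geodesicDistance(c(0, 0), c(3, 4), frame = "planar")  # 5
#' @export
geodesicDistance <- function(a, b, frame = c("planar", "geographic"),
                             radius = EARTH_RADIUS_M) {
  frame <- match.arg(frame)
  a <- asPosMatrix(a); b <- asPosMatrix(b)
  if (frame == "planar") {
    sqrt((a[, 1] - b[, 1])^2 + (a[, 2] - b[, 2])^2)
  } else {
    as.numeric(geosphere::distHaversine(a, b, r = radius))
  }
}

#' Compass bearing from one position to another
#'
#' Bearing in degrees clockwise from geographic north, in `[0, 360)`:
#' 0 = north, 90 = east. In the planar frame this is `atan2(dx, dy)`;
#' in the geographic frame it is the initial great-circle azimuth.
#'
#' @inheritParams geodesicDistance
#' @return bearing(s) in degrees in `[0, 360)`; `NA` where `a == b`
#'   (bearing undefined), with a warning.
#' @examples
#' compassBearing(c(0, 0), c(0, 100), frame = "planar")   # 0 (due north)
#' compassBearing(c(0, 0), c(100, 0), frame = "planar")   # 90 (due east)
#' @export
compassBearing <- function(a, b, frame = c("planar", "geographic")) {
  frame <- match.arg(frame)
  a <- asPosMatrix(a); b <- asPosMatrix(b)
  if (frame == "planar") {
    dx <- b[, 1] - a[, 1]; dy <- b[, 2] - a[, 2]
    out <- rad2deg(atan2(dx, dy))
    bad <- dx == 0 & dy == 0
  } else {
    # initial great-circle azimuth on the sphere
    p1 <- deg2rad(a[, 2]); p2 <- deg2rad(b[, 2])
    dl <- deg2rad(b[, 1] - a[, 1])
    y <- sin(dl) * cos(p2)
    x <- cos(p1) * sin(p2) - sin(p1) * cos(p2) * cos(dl)
    out <- rad2deg(atan2(y, x))
    bad <- a[, 1] == b[, 1] & a[, 2] == b[, 2]
  }
  if (any(bad)) {
    warning("bearing undefined for coincident positions; NA returned", call. = FALSE)
    out[bad] <- NA_real_
  }
  wrap360(out)
}
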