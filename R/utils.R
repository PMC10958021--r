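# Internal angle and seed helpers. Degrees are the external unit everywhere;
# radians appear only inside computations.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles to [0, 360)
#'
#' @param x angles in degrees.
#' @return angles in degrees wrapped to `[0, 360)`.
#' @export
wrap360 <- function(x) {
  out <- x %% 360
  # -1e-15 %% 360 can return 360 exactly under floating point
  out[out >= 360] <- out[out >= 360] - 360
  out
}

#' Wrap angles to (-180, 180]
#'
#' @param x angles in degrees.
#' @return angles in degrees wrapped to `(-180, 180]`.
#' @export
wrap180 <- function(x) {
  out <- wrap360(x)
  out[out > 180] <- out[out > 180] - 360
  out
}

# Signed circular difference a - b wrapped to (-180, 180].
circDiff <- function(a, b) wrap180(a - b)

# Deterministic per-stage substream: a stage name is hashed onto an integer
# offset so that pipeline stages draw from independent, individually
# reproducible streams derived from the single user seed.
deriveSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

# Consistent warning channel: every excluded record class warns once with a count.
notifyDrop <- function(what, n) {
  if (n > 0) warning(sprintf("%d %s excluded", n, what), call. = FALSE)
  invisible(n)
}
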