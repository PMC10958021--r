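# Penalized-contrast (Lavielle) change-point segmentation of a 1-D movement
# series: within-segment contrast from prefix sums, a dynamic program for the
# optimal partition into exactly K segments of minimum length lmin, and the
# normalized contrast-decrease rule for choosing K.

#' Segmentation configuration
#'
#' @param lmin minimum segment length in steps (>= 2).
#' @param kmax maximum number of segments (lowered with a warning when
#'   `kmax * lmin` exceeds the series length).
#' @param contrastType `"mean"` (squared deviations from the segment mean,
#'   the default and the choice suited to level shifts in step length),
#'   `"var"` (log-variance about the global mean, for pure dispersion
#'   changes), or `"meanvar"` (Gaussian log-likelihood contrast, mean and
#'   variance both free per segment).
#' @param seriesVariable which step-series column to segment (default
#'   `"step_length_m"`, a speed proxy under near-regular sampling).
#' @param S selection threshold for the normalized contrast decrease
#'   (default 0.75, the published recommendation).
#' @param padLastD also define D at K = kmax as the first difference
#'   `Jtilde(kmax-1) - Jtilde(kmax)` (alternative convention; default off,
#'   i.e. the strict second-difference rule).
#' @return a list of class `"SegmentationConfig"`.
#' @export
segmentationConfig <- function(lmin = 4L, kmax = 4L,
                               contrastType = c("mean", "var", "meanvar"),
                               seriesVariable = "step_length_m",
                               S = 0.75, padLastD = FALSE) {
  contrastType <- match.arg(contrastType)
  stopifnot(lmin >= 2, kmax >= 1, S > 0, S < 1)
  structure(list(lmin = as.integer(lmin), kmax = as.integer(kmax),
                 contrastType = contrastType, seriesVariable = seriesVariable,
                 S = S, padLastD = padLastD),
            class = "SegmentationConfig")
}

prefixSums <- function(y) {
  list(n = length(y), s1 = c(0, cumsum(y)), s2 = c(0, cumsum(y^2)),
       mu = mean(y))
}

# Contrast of the half-open segment [i, j) (1-based; observations i..j-1),
# vectorized over i. ps is prefixSums(y).
contrastPS <- function(ps, i, j, type, eps = 1e-12) {
  L <- j - i
  sum1 <- ps$s1[j] - ps$s1[i]
  sum2 <- ps$s2[j] - ps$s2[i]
  ssAboutMean <- sum2 - sum1^2 / L
  switch(type,
    mean = ssAboutMean,
    var = {
      ssGlobal <- sum2 - 2 * ps$mu * sum1 + L * ps$mu^2
      L * log(pmax(ssGlobal / L, eps))
    },
    meanvar = L * log(pmax(ssAboutMean / L, eps))
  )
}

#' Within-segment contrast
#'
#' Contrast of the half-open segment `[i, j)` of `series` (observations
#' `i .. j-1`, 1-based), computed in O(1) from prefix sums. See
#' [segmentationConfig()] for the three contrast types.
#'
#' @param series numeric vector.
#' @param i,j segment bounds, `1 <= i < j <= length(series) + 1`.
#' @param contrastType `"mean"`, `"var"` or `"meanvar"`.
#' @return the contrast value (single numeric).
#' @examples
#' segContrast(c(0, 10), 1, 3)  # mean 5: (-5)^2 + 5^2 = 50
#' @export
segContrast <- function(series, i, j, contrastType = c("mean", "var", "meanvar")) {
  contrastType <- match.arg(contrastType)
  stopifnot(i >= 1, j > i, j <= length(series) + 1)
  contrastPS(prefixSums(series), i, j, contrastType)
}

#' Optimal partitions for every K
#'
#' Dynamic program over prefix optima: for each K = 1..kmax and each prefix,
#' the minimal total contrast over partitions into exactly K contiguous
#' segments each of length >= lmin. Ties are broken toward the earliest
#' (smallest-index) last boundary for reproducibility.
#'
#' @param series numeric vector of length >= lmin.
#' @param config a [segmentationConfig()].
#' @return list with `J` (numeric, `J[K]` = full-series optimum for K
#'   segments), `kmax` (possibly lowered), and `boundariesFor(K)`, a
#'   function returning the K x 2 half-open boundary matrix for any K.
#' @export
optimalPartitions <- function(series, config = segmentationConfig()) {
  n <- length(series)
  lmin <- config$lmin
  kmax <- config$kmax
  if (n < lmin) stop("series shorter than lmin", call. = FALSE)
  if (kmax * lmin > n) {
    kmax <- max(1L, n %/% lmin)
    warning(sprintf("kmax lowered to %d (kmax * lmin exceeded series length)",
                    kmax), call. = FALSE)
  }
  ps <- prefixSums(series)
  type <- config$contrastType
  # V[k, j]: optimal contrast of prefix [1, j) split into k segments;
  # j indexes 2..n+1. B[k, j]: start index of the last segment.
  V <- matrix(Inf, nrow = kmax, ncol = n + 1)
  B <- matrix(NA_integer_, nrow = kmax, ncol = n + 1)
  js <- (lmin + 1):(n + 1)
  V[1, js] <- contrastPS(ps, 1L, js, type)
  B[1, js] <- 1L
  if (kmax >= 2) {
    for (k in 2:kmax) {
      for (j in (k * lmin + 1):(n + 1)) {
        # last segment [i, j) with i ranging over feasible starts
        is <- ((k - 1) * lmin + 1):(j - lmin)
        tot <- V[k - 1, is] + contrastPS(ps, is, j, type)
        best <- which.min(tot)  # first minimum = earliest boundary
        V[k, j] <- tot[best]
        B[k, j] <- is[best]
      }
    }
  }
  J <- V[, n + 1]
  Bmat <- B
  boundariesFor <- function(K) {
    stopifnot(K >= 1, K <= kmax)
    ends <- integer(K + 1)
    ends[K + 1] <- n + 1L
    for (k in K:1) {
      ends[k] <- Bmat[k, ends[k + 1]]
    }
    cbind(start = ends[1:K], end = ends[2:(K + 1)])
  }
  list(J = J, kmax = kmax, boundariesFor = boundariesFor)
}

#' Choose the number of segments from the contrast curve
#'
#' The optimal contrast curve is normalized to
#' `Jtilde(K) = (J(kmax) - J(K)) / (J(kmax) - J(1)) * (kmax - 1) + 1`
#' (so `Jtilde(1) = kmax`, `Jtilde(kmax) = 1`) and its second differences
#' `D(K) = Jtilde(K-1) - 2 Jtilde(K) + Jtilde(K+1)` (K = 2..kmax-1) measure
#' where the curve stops dropping. The chosen K is the largest K with
#' `D(K) > S`; when no D exceeds S (or the curve is flat), K = 1.
#'
#' @param J numeric contrast curve, `J[K]` for K = 1..kmax.
#' @param S selection threshold in (0, 1).
#' @param padLastD see [segmentationConfig()].
#' @return list with `chosenK` and `D` (the difference curve, `NA` where
#'   undefined).
#' @export
chooseK <- function(J, S = 0.75, padLastD = FALSE) {
  kmax <- length(J)
  D <- rep(NA_real_, kmax)
  if (kmax < 2 || abs(J[kmax] - J[1]) < .Machine$double.eps * max(1, abs(J[1])))
    return(list(chosenK = 1L, D = D))
  Jt <- (J[kmax] - J) / (J[kmax] - J[1]) * (kmax - 1) + 1
  if (kmax >= 3)
    D[2:(kmax - 1)] <- Jt[1:(kmax - 2)] - 2 * Jt[2:(kmax - 1)] + Jt[3:kmax]
  if (padLastD)
    D[kmax] <- Jt[kmax - 1] - Jt[kmax]
  hits <- which(!is.na(D) & D > S)
  list(chosenK = if (length(hits)) max(hits) else 1L, D = D)
}

#' Segment a track's step series
#'
#' Builds the configured per-step series (default: step lengths), runs the
#' dynamic program and the choose-K rule, and reconstructs the boundaries of
#' the chosen partition. A chosen K of 1 returns the whole series as one
#' segment.
#'
#' @param track a [Track-class] (or a plain numeric series).
#' @param config a [segmentationConfig()].
#' @return a [SegmentationResult-class].
#' @export
segmentTrack <- function(track, config = segmentationConfig()) {
  if (is(track, "Track")) {
    series <- stepSeries(track)[[config$seriesVariable]]
    eid <- eventId(track)
  } else {
    series <- as.numeric(track)
    eid <- NA_character_
  }
  op <- optimalPartitions(series, config)
  ck <- chooseK(op$J, config$S, config$padLastD)
  K <- min(ck$chosenK, op$kmax)
  new("SegmentationResult", eventId = eid, chosenK = as.integer(K),
      boundaries = op$boundariesFor(K), Jcurve = op$J, Dcurve = ck$D,
      series = series)
}
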