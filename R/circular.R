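# Circular descriptive and inferential statistics for homeward bearings.
# Angles are degrees externally, radians internally. The directedness test
# represents each bearing as (cos, sin) and asks whether the bivariate mean
# differs from the origin; the mixed variant adds a per-animal random
# intercept to both components to absorb repeated translocations of the
# same individual.

#' Mean vector of a circular sample
#'
#' @param anglesDeg angles in degrees.
#' @return list with `mean_angle_deg` (in `[0, 360)`, `NA` when `r = 0`,
#'   where the mean direction is undefined) and `r`, the mean resultant
#'   length in `[0, 1]`.
#' @examples
#' meanVector(c(0, 90))  # r = sqrt(2)/2, mean 45
#' @export
meanVector <- function(anglesDeg) {
  stopifnot(length(anglesDeg) >= 1, !anyNA(anglesDeg))
  th <- deg2rad(anglesDeg)
  C <- mean(cos(th)); S <- mean(sin(th))
  r <- sqrt(C^2 + S^2)
  mu <- if (r < 1e-12) NA_real_ else wrap360(rad2deg(atan2(S, C)))
  list(mean_angle_deg = mu, r = min(r, 1))
}

#' Rayleigh test of circular uniformity
#'
#' Classical test based on Z = n r^2 with the standard series approximation
#' for the p-value. Used as the non-hierarchical reference test; the
#' repeated-measures analysis uses [manovaDirectedness()].
#'
#' @param anglesDeg angles in degrees (n >= 1; a warning is issued below
#'   n = 4, where the approximation is rough).
#' @return list with `n`, `mean_angle_deg`, `r`, `statistic` (Z), `p_value`,
#'   `method = "rayleigh"`.
#' @export
rayleighTest <- function(anglesDeg) {
  n <- length(anglesDeg)
  if (n < 1) stop("rayleighTest needs at least one angle", call. = FALSE)
  if (n < 4) warning("Rayleigh p-value approximation is unreliable for n < 4",
                     call. = FALSE)
  mv <- meanVector(anglesDeg)
  Z <- n * mv$r^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  list(n = n, mean_angle_deg = mv$mean_angle_deg, r = mv$r, statistic = Z,
       p_value = min(max(p, 0), 1), method = "rayleigh")
}

# Hotelling one-sample T2 of the (cos, sin) pairs against the origin,
# F-transformed with df = (2, n - 2).
hotellingDirectedness <- function(th) {
  n <- length(th)
  X <- cbind(cos(th), sin(th))
  m <- colMeans(X)
  S <- stats::cov(X)
  det_ok <- is.finite(determinant(S)$modulus) && abs(det(S)) > 1e-300
  if (!det_ok) {
    # degenerate sample (e.g. all bearings identical): any nonzero mean is
    # infinitely far from the origin in Mahalanobis terms
    T2 <- if (sqrt(sum(m^2)) > 1e-12) Inf else 0
  } else {
    T2 <- n * drop(t(m) %*% solve(S, m))
  }
  Fstat <- (n - 2) / (2 * (n - 1)) * T2
  p <- stats::pf(Fstat, 2, n - 2, lower.tail = FALSE)
  list(statistic = Fstat, p_value = p, df = c(2, n - 2))
}

# Intercept-only random-intercept fit of one component; returns the fixed
# intercept, its standard error, and the Satterthwaite denominator df.
# Degenerate fits (e.g. zero residual variance) fall back from lmerTest's
# Satterthwaite machinery to the lme4 fit with df = n - 1.
fitComponent <- function(y, cluster) {
  df <- data.frame(y = y, cluster = factor(cluster))
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore")
  res <- tryCatch(suppressWarnings(suppressMessages({
    fit <- lmerTest::lmer(y ~ 1 + (1 | cluster), data = df, REML = TRUE,
                          control = ctrl)
    co <- stats::coef(summary(fit))
    list(b = co[1, "Estimate"], se = co[1, "Std. Error"], df = co[1, "df"])
  })), error = function(e) NULL)
  if (!is.null(res) && is.finite(res$df) && res$df > 0 && is.finite(res$se))
    return(res)
  res <- tryCatch(suppressWarnings(suppressMessages({
    fit <- lme4::lmer(y ~ 1 + (1 | cluster), data = df, REML = TRUE,
                      control = ctrl)
    co <- stats::coef(summary(fit))
    list(b = co[1, "Estimate"], se = co[1, "Std. Error"], df = length(y) - 1)
  })), error = function(e) NULL)
  if (!is.null(res) && !is.finite(res$se)) res <- NULL
  if (!is.null(res)) return(res)
  # fully degenerate response (e.g. zero variance): plain mean and its SE
  list(b = mean(y), se = stats::sd(y) / sqrt(length(y)), df = length(y) - 1)
}

#' MANOVA-type test of directedness, with optional per-animal random intercept
#'
#' Tests whether a bearing distribution has a nonzero mean direction by
#' modelling the (cos, sin) components. Without a random intercept this is
#' the one-sample Hotelling T-squared test of the bivariate mean against the
#' origin. With a random intercept, each component is fit as an
#' intercept-only linear mixed model (random intercept per cluster, REML via
#' lme4) and the joint null that both fixed intercepts are zero is tested
#' with a 2-df Wald statistic from the estimated intercepts and their
#' standard errors, the components treated as independent (which holds under
#' the uniform null). The default reference distribution is
#' F(2, df) with Satterthwaite denominator df averaged over the two
#' component fits — at study sizes of a few dozen bearings the asymptotic
#' chi-square(2) reference is anticonservative; `reference = "chisq"` selects
#' it anyway.
#'
#' Distributions with fewer than 5 bearings are not tested: the returned
#' object carries `status = "insufficient_n"` and no p-value. When every
#' cluster holds a single bearing the random intercept is unidentifiable
#' (it shrinks to zero) and the mixed variant reduces to the pooled
#' Hotelling test, flagged in a `note` field.
#'
#' @param anglesDeg bearings in degrees.
#' @param clusterIds cluster (animal) identifier per bearing; required when
#'   `useRandomIntercept = TRUE`.
#' @param useRandomIntercept add the per-cluster random intercept?
#' @param reference `"satterthwaite"` (default) or `"chisq"` for the mixed
#'   variant's null reference.
#' @return list with `n`, `mean_angle_deg`, `r`, `statistic`, `p_value`,
#'   `method` (`"manova"` or `"mixed_manova"`), `status`
#'   (`"ok" | "insufficient_n" | "undefined_mean"`).
#' @export
manovaDirectedness <- function(anglesDeg, clusterIds = NULL,
                               useRandomIntercept = !is.null(clusterIds),
                               reference = c("satterthwaite", "chisq")) {
  reference <- match.arg(reference)
  n <- length(anglesDeg)
  mv <- if (n >= 1) meanVector(anglesDeg) else list(mean_angle_deg = NA_real_, r = NA_real_)
  base <- list(n = n, mean_angle_deg = mv$mean_angle_deg, r = mv$r,
               statistic = NA_real_, p_value = NA_real_,
               method = if (useRandomIntercept) "mixed_manova" else "manova",
               status = "ok")
  if (n < 5) {
    base$status <- "insufficient_n"
    return(base)
  }
  th <- deg2rad(anglesDeg)
  if (!useRandomIntercept) {
    ht <- hotellingDirectedness(th)
    base$statistic <- ht$statistic
    base$p_value <- ht$p_value
    return(base)
  }
  if (is.null(clusterIds) || length(clusterIds) != n)
    stop("clusterIds (one per bearing) required for the mixed variant",
         call. = FALSE)
  if (all(table(clusterIds) == 1L)) {
    # one bearing per cluster: the random intercept is unidentifiable and
    # shrinks to zero, so the test reduces to the pooled one
    ht <- hotellingDirectedness(th)
    base$statistic <- ht$statistic
    base$p_value <- ht$p_value
    base$note <- "random intercept unidentifiable (one bearing per cluster); pooled test used"
    return(base)
  }
  fc <- fitComponent(cos(th), clusterIds)
  fs <- fitComponent(sin(th), clusterIds)
  if (fc$se < 1e-12 || fs$se < 1e-12) {
    # degenerate (all bearings identical): mean is trivially nonzero
    base$statistic <- Inf
    base$p_value <- 0
    return(base)
  }
  W <- (fc$b / fc$se)^2 + (fs$b / fs$se)^2
  if (reference == "chisq") {
    base$statistic <- W
    base$p_value <- stats::pchisq(W, df = 2, lower.tail = FALSE)
  } else {
    dfDen <- mean(c(fc$df, fs$df))
    base$statistic <- W / 2
    base$p_value <- stats::pf(W / 2, 2, dfDen, lower.tail = FALSE)
  }
  base
}

#' Bootstrap confidence interval for the mean direction
#'
#' Percentile interval on the circle: resampled mean angles are centered at
#' the observed mean, the central 1 - alpha arc of the deviations is taken,
#' and mapped back. Resampling units are clusters (animals, all their
#' bearings kept together) by default, matching the random-intercept logic;
#' `cluster = FALSE` resamples individual bearings.
#'
#' @param anglesDeg bearings in degrees (n >= 5).
#' @param clusterIds cluster id per bearing (required when `cluster = TRUE`).
#' @param B number of bootstrap resamples (>= 100 enforced).
#' @param alpha interval level is 1 - alpha.
#' @param cluster resample clusters rather than bearings?
#' @param seed integer seed for the resampling stream.
#' @return list with `ci_low_deg`, `ci_high_deg` (degrees in `[0, 360)`,
#'   `NA` with a warning when the observed mean direction is undefined),
#'   `B`, `alpha`.
#' @export
bootstrapMeanCI <- function(anglesDeg, clusterIds = NULL, B = 10000,
                            alpha = 0.05, cluster = !is.null(clusterIds),
                            seed = 1L) {
  n <- length(anglesDeg)
  if (n < 5) stop("bootstrapMeanCI needs at least 5 bearings", call. = FALSE)
  if (B < 100) stop("B must be at least 100", call. = FALSE)
  mv <- meanVector(anglesDeg)
  if (is.na(mv$mean_angle_deg)) {
    warning("mean direction undefined (r = 0); CI not computed", call. = FALSE)
    return(list(ci_low_deg = NA_real_, ci_high_deg = NA_real_, B = B, alpha = alpha))
  }
  th <- deg2rad(anglesDeg)
  set.seed(seed)
  if (cluster) {
    if (is.null(clusterIds)) stop("clusterIds required for cluster bootstrap",
                                  call. = FALSE)
    byCl <- split(seq_len(n), clusterIds)
    k <- length(byCl)
    means <- vapply(seq_len(B), function(b) {
      idx <- unlist(byCl[sample.int(k, k, replace = TRUE)], use.names = FALSE)
      atan2(mean(sin(th[idx])), mean(cos(th[idx])))
    }, numeric(1))
  } else {
    idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
    means <- atan2(rowMeans(matrix(sin(th)[idx], nrow = B)),
                   rowMeans(matrix(cos(th)[idx], nrow = B)))
  }
  dev <- wrap180(rad2deg(means) - mv$mean_angle_deg)
  qs <- stats::quantile(dev, c(alpha / 2, 1 - alpha / 2), names = FALSE,
                        type = 7)
  list(ci_low_deg = wrap360(mv$mean_angle_deg + qs[1]),
       ci_high_deg = wrap360(mv$mean_angle_deg + qs[2]),
       B = B, alpha = alpha)
}

#' Per-ring circular statistics table
#'
#' For each subset (all / homed / not homed) and ring, computes n, the mean
#' vector, and the directedness test; bootstrap CIs are added for
#' distributions that are significant at `alpha` (mirroring the convention
#' of reporting CIs only for directed distributions), or always when
#' `forceCI = TRUE`. Rings with fewer than `minN` bearings are reported with
#' status `insufficient_n` and no test.
#'
#' @param outcomes data.frame from [homingOutcomes()].
#' @param minN minimum bearings for testing (default 5).
#' @param useRandomIntercept use the mixed directedness test?
#' @param B,alpha bootstrap parameters, see [bootstrapMeanCI()].
#' @param seed integer seed for bootstrap streams.
#' @param forceCI compute CIs regardless of significance.
#' @param reference see [manovaDirectedness()].
#' @return data.frame with one row per (subset, ring): `subset`, `ring`,
#'   `n`, `mean_angle_deg`, `r`, `method`, `statistic`, `p`, `ci_low`,
#'   `ci_high`, `status`.
#' @export
ringStats <- function(outcomes, minN = 5, useRandomIntercept = TRUE,
                      B = 10000, alpha = 0.05, seed = 1L, forceCI = FALSE,
                      reference = c("satterthwaite", "chisq")) {
  reference <- match.arg(reference)
  rows <- list()
  for (subset in c("all", "homed", "not_homed")) {
    bt <- bearingTable(outcomes, subset)
    for (ring in sort(unique(bt$ring))) {
      sub <- bt[bt$ring == ring, , drop = FALSE]
      n <- nrow(sub)
      row <- data.frame(subset = subset, ring = ring, n = n,
                        mean_angle_deg = NA_real_, r = NA_real_,
                        method = NA_character_, statistic = NA_real_,
                        p = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                        status = "ok")
      if (n >= 1) {
        mv <- meanVector(sub$home_relative_deg)
        row$mean_angle_deg <- mv$mean_angle_deg
        row$r <- mv$r
      }
      if (n < minN) {
        row$status <- "insufficient_n"
      } else if (is.na(row$mean_angle_deg)) {
        row$status <- "undefined_mean"
      } else {
        dt <- manovaDirectedness(sub$home_relative_deg, sub$animal_id,
                                 useRandomIntercept, reference)
        row$method <- dt$method
        row$statistic <- dt$statistic
        row$p <- dt$p_value
        if (forceCI || (!is.na(dt$p_value) && dt$p_value < alpha)) {
          ci <- bootstrapMeanCI(sub$home_relative_deg, sub$animal_id, B, alpha,
                                cluster = useRandomIntercept,
                                seed = deriveSeed(seed, paste0("ci_", subset, "_", ring)))
          row$ci_low <- ci$ci_low_deg
          row$ci_high <- ci$ci_high_deg
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
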