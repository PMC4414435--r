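# Comparison statistics for axial orientation data: deviation angles,
# robust summaries, quadrant rose histograms, eigenvalue-ratio
# (sorting-confidence) distributions, and transmural profiles.

#' Deviation angle between two axial unit vectors
#'
#' \eqn{\mathrm{acos}(\min(1, |a \cdot b|))} in degrees, in [0, 90]. Axial
#' vectors are sign-free, so the absolute dot product makes the angle
#' invariant under flipping either argument.
#'
#' @param a,b unit vectors: length-3 vectors or n x 3 matrices (rows paired).
#' @return Angle(s) in degrees in [0, 90]; NA for zero-length input rows.
#' @export
axialAngle <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, 1)
  if (is.null(dim(b))) b <- matrix(b, 1)
  la <- sqrt(rowSums(a^2)); lb <- sqrt(rowSums(b^2))
  d <- abs(rowSums(a * b)) / (la * lb)
  ang <- .rad2deg(acos(pmin(1, d)))
  ang[la == 0 | lb == 0] <- NA_real_
  drop(ang)
}

#' Circular difference of two fold-180 angles
#'
#' Distance between two angles that are periodic with period 180 degrees
#' (e.g. helix angles of axial vectors):
#' \eqn{d = \min(|x-y|, 180-|x-y|)}, in [0, 90].
#'
#' @param x,y angles in degrees in (-90, 90]; vectorized.
#' @return Differences in degrees in [0, 90].
#' @export
anglePairDifference <- function(x, y) {
  d <- abs(x - y)
  pmin(d, 180 - d)
}

#' Robust summary of a sample
#'
#' Median, raw median absolute deviation (MAD without the normal-consistency
#' factor), interquartile range (linear-interpolation quantiles), mean and
#' SD (n-1 denominator). NAs are dropped.
#'
#' @param values numeric vector with at least one finite value.
#' @return Named list: \code{median, mad, iqr, mean, sd, n}.
#' @export
summarizeAngles <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("no finite values to summarize")
  med <- median(values)
  list(median = med,
       mad = median(abs(values - med)),
       iqr = unname(diff(quantile(values, c(0.25, 0.75), type = 7))),
       mean = mean(values),
       sd = if (length(values) > 1L) sd(values) else 0,
       n = length(values))
}

#' Quadrant rose histogram of deviation angles
#'
#' Equal-width binning of deviation angles over [0, 90] degrees (the range of
#' axial deviation angles), bins closed on the left and the last bin closed
#' on the right, so counts always sum to the sample size.
#'
#' @param deviations angles in degrees, all within [0, 90].
#' @param nBins number of equal-width bins.
#' @return data.frame with \code{binStart}, \code{binEnd}, \code{count}.
#' @export
quadrantRose <- function(deviations, nBins = 9L) {
  deviations <- deviations[!is.na(deviations)]
  if (any(deviations < 0 | deviations > 90))
    stop("deviation angles must lie in [0, 90] degrees")
  breaks <- seq(0, 90, length.out = nBins + 1L)
  idx <- pmin(findInterval(deviations, breaks, rightmost.closed = TRUE),
              nBins)
  data.frame(binStart = breaks[-(nBins + 1L)], binEnd = breaks[-1L],
             count = tabulate(idx, nbins = nBins))
}

# axial (period-180) circular mean and dispersion via angle doubling
.axialCircular <- function(deg) {
  z <- .deg2rad(deg * 2)
  C <- mean(cos(z)); S <- mean(sin(z))
  R <- sqrt(C^2 + S^2)
  meanA <- .fold180(.rad2deg(atan2(S, C)) / 2)
  sdA <- if (R > 0) .rad2deg(sqrt(-2 * log(R))) / 2 else Inf
  list(mean = meanA, sd = sdA, R = R)
}

#' Transmural profile of an angle map
#'
#' Bins voxels by normalized transmural depth and summarizes each bin with
#' the axial circular mean (period 180 degrees, computed by the
#' angle-doubling construction) and the matching circular SD. Empty bins are
#' returned with NA and flagged.
#'
#' @param angles angles in degrees in (-90, 90] (vector or array).
#' @param depth normalized transmural depth in [0, 1], same length.
#' @param nBins number of equal-width depth bins.
#' @return data.frame with \code{depthMid}, \code{mean}, \code{sd},
#'   \code{n}, \code{empty}.
#' @export
transmuralProfile <- function(angles, depth, nBins = 10L) {
  a <- as.vector(angles); dpt <- as.vector(depth)
  ok <- is.finite(a) & is.finite(dpt)
  a <- a[ok]; dpt <- dpt[ok]
  breaks <- seq(0, 1, length.out = nBins + 1L)
  idx <- pmin(findInterval(dpt, breaks, rightmost.closed = TRUE), nBins)
  out <- data.frame(depthMid = (breaks[-1L] + breaks[-(nBins + 1L)]) / 2,
                    mean = NA_real_, sd = NA_real_, n = 0L, empty = TRUE)
  for (b in seq_len(nBins)) {
    vals <- a[idx == b]
    if (length(vals)) {
      cc <- .axialCircular(vals)
      out$mean[b] <- cc$mean; out$sd[b] <- cc$sd
      out$n[b] <- length(vals); out$empty[b] <- FALSE
    }
  }
  out
}

#' Eigenvalue sorting-confidence distribution
#'
#' Per-voxel percentage ratio of the eigenvalue pair that controls whether
#' two eigenvectors can be told apart, for the named structural feature:
#' under the DTI convention the laminar pair is (lambda2, lambda3) and the
#' myocyte pair (lambda1, lambda2); under the structure-tensor convention
#' the laminar pair is (lambda1, lambda2) and the myocyte pair
#' (lambda2, lambda3). 100 percent means identical eigenvalues (no sorting
#' confidence).
#'
#' @param field an \code{OrientationField} with convention \code{"st"} or
#'   \code{"dti"}.
#' @param feature \code{"laminar"} or \code{"myocyte"}.
#' @param cutoffs ratio cutoffs (percent); the fraction of voxels at or
#'   above each cutoff is reported.
#' @param select optional logical array restricting the voxels used.
#' @return List with \code{ratios} (3D array of percentages),
#'   \code{summary} (from \code{\link{summarizeAngles}}) and
#'   \code{fractionAbove} (named fractions per cutoff).
#' @export
eigenConfidence <- function(field, feature = c("laminar", "myocyte"),
                            cutoffs = c(85, 95), select = NULL) {
  stopifnot(is(field, "OrientationField"))
  feature <- match.arg(feature)
  if (field@convention == "truth")
    stop("sorting confidence is undefined for ground-truth fields")
  pair <- if (field@convention == "dti") {
    if (feature == "laminar") c(3L, 2L) else c(2L, 1L)
  } else {
    if (feature == "laminar") c(2L, 1L) else c(3L, 2L)
  }
  small <- field@values[, , , pair[1]]
  large <- field@values[, , , pair[2]]
  ratios <- eigenvalueRatio(small, large)
  use <- if (is.null(select)) ratios else ifelse(select, ratios, NA_real_)
  v <- use[is.finite(use)]
  frac <- vapply(cutoffs, function(ct) mean(v >= ct), numeric(1))
  list(ratios = ratios, summary = summarizeAngles(v),
       fractionAbove = setNames(frac, paste0(">=", cutoffs, "%")))
}
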