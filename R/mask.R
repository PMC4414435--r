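# Fine-detail tissue mask: intensity thresholding followed by a slice-wise
# 2D morphological sequence (clean, bridge, fill, open, thicken). Tissue is
# dark in contrast-enhanced volumes, so thresholding keeps low intensities.

.shift2 <- function(m, di, dj) {
  # zero-padded shift: result[i,j] = m[i+di, j+dj]
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  si <- seq_len(nr) + di
  sj <- seq_len(nc) + dj
  okI <- si >= 1L & si <= nr
  okJ <- sj >= 1L & sj <= nc
  out[okI, okJ] <- m[si[okI], sj[okJ]]
  out
}

# 8-neighbourhood offsets in cyclic order around the centre (consecutive
# entries are themselves 8-adjacent), used for neighbour counts and for the
# ring-component count in bridge.
.ring <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
               c(1, 1), c(1, 0), c(1, -1), c(0, -1))

.neighbourStack <- function(m) {
  lapply(seq_len(8), function(k) .shift2(m, .ring[k, 1], .ring[k, 2]))
}

#' Threshold a volume into a tissue mask
#'
#' A voxel is classified as tissue when its intensity is at most
#' \code{fraction} of the reference intensity (tissue is dark in
#' contrast-enhanced gradient-echo imaging, where the contrast agent fills
#' the interstices). The reference is the 99.5th-percentile intensity, a
#' robust maximum insensitive to isolated hot voxels.
#'
#' @param volume an \code{ImageVolume}.
#' @param fraction intensity fraction in [0, 1]; default 0.20.
#' @return A \code{TissueMask}; a provenance record stores the fraction and
#'   reference intensity. An empty mask sets a warning flag in the
#'   provenance rather than failing.
#' @export
thresholdMask <- function(volume, fraction = 0.20) {
  stopifnot(is(volume, "ImageVolume"))
  if (fraction < 0 || fraction > 1) stop("'fraction' must be in [0, 1]")
  v <- voxels(volume)
  if (!all(is.finite(v))) stop("volume intensities must be finite")
  ref <- as.numeric(quantile(v, 0.995, names = FALSE))
  m <- v <= fraction * ref
  if (!any(m)) warning("threshold produced an empty tissue mask")
  new("TissueMask", mask = m, spacing = voxelSpacing(volume),
      provenance = list(fraction = fraction, reference = ref,
                        empty = !any(m), operations = "threshold"))
}

#' Individual 2D binary morphology operations
#'
#' The slice-wise operations applied (in order) by \code{\link{morphSequence}}
#' on 2D binary matrices (1 = foreground):
#' \describe{
#'   \item{\code{morphClean}}{removes isolated foreground pixels (no
#'     foreground among the 8 neighbours). Never adds pixels.}
#'   \item{\code{morphBridge}}{sets a background pixel to foreground when its
#'     8-neighbourhood ring contains two or more foreground groups that are
#'     not mutually 8-adjacent within the ring (i.e. the pixel bridges
#'     locally disconnected foreground).}
#'   \item{\code{morphFill}}{fills isolated background pixels (all 8
#'     neighbours foreground). Never removes pixels.}
#'   \item{\code{morphOpen}}{binary opening (erosion then dilation) with a
#'     3x3 box structuring element.}
#'   \item{\code{morphThicken}}{one growth iteration: adds background pixels
#'     that touch exactly one 8-connected foreground component, so two
#'     previously disconnected components are never merged.}
#' }
#'
#' @param m 2D integer/logical matrix, nonzero = foreground.
#' @return Integer 0/1 matrix of the same size.
#' @name morphology
NULL

#' @rdname morphology
#' @export
morphClean <- function(m) {
  m <- (m != 0) + 0L
  nb <- Reduce(`+`, .neighbourStack(m))
  m * (1L - (m == 1L & nb == 0L))
}

#' @rdname morphology
#' @export
morphBridge <- function(m) {
  m <- (m != 0) + 0L
  ring <- .neighbourStack(m)
  # number of cyclic foreground blocks around the pixel = number of
  # rising transitions background -> foreground in cyclic order
  trans <- matrix(0L, nrow(m), ncol(m))
  for (k in seq_len(8)) {
    prev <- ring[[if (k == 1) 8 else k - 1]]
    trans <- trans + (ring[[k]] == 1L & prev == 0L)
  }
  add <- m == 0L & trans >= 2L
  m + add
}

#' @rdname morphology
#' @export
morphFill <- function(m) {
  m <- (m != 0) + 0L
  nb <- Reduce(`+`, .neighbourStack(m))
  m + (m == 0L & nb == 8L)
}

#' @rdname morphology
#' @export
morphOpen <- function(m) {
  m <- (m != 0) + 0L
  # erosion then dilation with a 3x3 box; outside the image is background
  er <- matrix(1L, nrow(m), ncol(m))
  for (k in seq_len(8)) er <- er & .shift2(m, .ring[k, 1], .ring[k, 2])
  er <- (er & m) + 0L
  di <- er
  for (k in seq_len(8)) di <- di | .shift2(er, .ring[k, 1], .ring[k, 2])
  di + 0L
}

#' @rdname morphology
#' @export
morphThicken <- function(m) {
  m <- (m != 0) + 0L
  lab <- labelComponents2d(m)
  labNb <- function(x) lapply(seq_len(8), function(k)
    .shift2(x, .ring[k, 1], .ring[k, 2]))
  ring <- labNb(lab)
  lo <- hi <- matrix(0L, nrow(m), ncol(m))
  for (k in seq_len(8)) {
    r <- ring[[k]]
    lo <- ifelse(r > 0L & (lo == 0L | r < lo), r, lo)
    hi <- pmax(hi, r)
  }
  cand <- m == 0L & lo > 0L & lo == hi  # touches exactly one component
  # a pixel added next to an added pixel of another component would still
  # merge the two; exclude candidate pairs with different labels
  candLab <- ifelse(cand, lo, 0L)
  ringC <- labNb(candLab)
  ok <- cand
  for (k in seq_len(8)) {
    r <- ringC[[k]]
    ok <- ok & (r == 0L | r == candLab)
  }
  m + ok
}

#' 8-connected component labelling of a 2D binary matrix
#'
#' Iterative minimum-label propagation; suitable for the moderate slice sizes
#' handled here. Background is 0; foreground pixels receive positive integer
#' labels, one per 8-connected component.
#'
#' @param m 2D binary matrix.
#' @return Integer matrix of labels.
#' @export
labelComponents2d <- function(m) {
  fg <- m != 0
  lab <- matrix(0L, nrow(m), ncol(m))
  if (!any(fg)) return(lab)
  lab[fg] <- seq_len(sum(fg))
  repeat {
    best <- lab
    for (k in seq_len(8)) {
      r <- .shift2(lab, .ring[k, 1], .ring[k, 2])
      best <- ifelse(fg & r > 0L & r < best, r, best)
    }
    # merge via the label-equivalence table, with path compression, so
    # convergence takes O(log diameter) sweeps rather than O(diameter)
    f <- seq_len(max(lab))
    mins <- tapply(best[fg], lab[fg], min)
    f[as.integer(names(mins))] <- as.integer(mins)
    repeat {
      f2 <- f[f]
      if (identical(f2, f)) break
      f <- f2
    }
    newlab <- lab
    newlab[fg] <- f[lab[fg]]
    if (identical(newlab, lab)) break
    lab <- newlab
  }
  u <- sort(unique(lab[lab > 0L]))
  lab[lab > 0L] <- match(lab[lab > 0L], u)
  lab
}

#' Slice-wise morphological cleanup of a tissue mask
#'
#' Applies, slice by slice along the long axis (third dimension), the 2D
#' sequence clean, bridge, fill, open, thicken, in that order. The sequence
#' removes speckle, connects one-pixel gaps, fills pinholes, smooths the
#' outline, and finally grows the mask outward by one pixel without merging
#' previously unconnected objects.
#'
#' @param mask a \code{TissueMask}.
#' @return A \code{TissueMask} with updated provenance.
#' @export
morphSequence <- function(mask) {
  stopifnot(is(mask, "TissueMask"))
  a <- mask@mask
  for (k in seq_len(dim(a)[3])) {
    s <- a[, , k] + 0L
    s <- morphThicken(morphOpen(morphFill(morphBridge(morphClean(s)))))
    a[, , k] <- s != 0L
  }
  new("TissueMask", mask = a, spacing = mask@spacing,
      provenance = c(mask@provenance,
                     list(operations2 = c("clean", "bridge", "fill",
                                          "open", "thicken"))))
}
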