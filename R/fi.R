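# Direct laminar-normal measurement from an intensity isosurface: cubic
# upsampling, marching-tetrahedra surface extraction, partitioning of the
# surface into 200 um boxes aligned with the coarse acquisition grid, axial
# mean normals per box, and von Mises-Fisher concentration filtering.

# Natural cubic-spline interpolation matrix mapping n samples to the given
# positions (in 0-based sample-index units). Spline interpolation is linear
# in the data, so the map is a matrix; columns are spline cardinal functions.
.splineMatrix <- function(n, at) {
  if (n < 2L) return(matrix(1, length(at), n))
  M <- matrix(0, length(at), n)
  x <- seq_len(n) - 1
  for (j in seq_len(n)) {
    e <- numeric(n); e[j] <- 1
    M[, j] <- splinefun(x, e, method = "natural")(at)
  }
  M
}

.applyMatrixAxis <- function(vol, M, axis) {
  d <- dim(vol)
  perm <- c(axis, setdiff(1:3, axis))
  v <- aperm(vol, perm)
  dim(v) <- c(d[axis], prod(d[perm[2:3]]))
  out <- M %*% v
  dim(out) <- c(nrow(M), d[perm[2]], d[perm[3]])
  aperm(out, order(perm))
}

#' Upsample a volume by separable cubic-spline interpolation
#'
#' Interpolates the volume onto a grid refined by an integer factor along
#' each axis using natural cubic splines applied separably (tricubic
#' interpolation). Output voxel centres subdivide the input voxels, so the
#' output spacing is \code{spacing/factor} and the field of view is
#' preserved; values at refined centres outside the outermost input centres
#' are linearly extrapolated by the natural spline end conditions. Exact on
#' constant and linear intensity ramps.
#'
#' @param volume an \code{ImageVolume}.
#' @param factor integer upsampling factor (4 maps 50 um voxels to 12.5 um).
#' @return An \code{ImageVolume} with \code{factor^3} times as many voxels.
#' @export
upsampleVolume <- function(volume, factor = 4L) {
  stopifnot(is(volume, "ImageVolume"))
  factor <- as.integer(factor)
  if (factor < 1L) stop("'factor' must be a positive integer")
  if (factor == 1L) return(volume)
  d <- dim(volume)
  v <- voxels(volume)
  for (ax in 1:3) {
    n <- d[ax]
    at <- (seq_len(n * factor) - 0.5) / factor - 0.5   # 0-based index units
    v <- .applyMatrixAxis(v, .splineMatrix(n, at), ax)
  }
  ImageVolume(v, voxelSpacing(volume) / factor)
}

# Tetrahedral decomposition of the unit cube: corners numbered 0..7 with
# bits (x=1, y=2, z=4); six tetrahedra share the main diagonal 0-7.
.cubeTets <- local({
  paths <- rbind(c(1, 2, 4), c(1, 4, 2), c(2, 1, 4),
                 c(2, 4, 1), c(4, 1, 2), c(4, 2, 1))
  t(apply(paths, 1, function(p) c(0, p[1], p[1] + p[2], 7)))
})
.cornerOffsets <- cbind(x = bitwAnd(0:7, 1L),
                        y = bitwAnd(0:7, 2L) %/% 2L,
                        z = bitwAnd(0:7, 4L) %/% 4L)

#' Extract an isosurface mesh by marching tetrahedra
#'
#' Generates the triangulated surface where the volume crosses the given
#' intensity threshold. Each grid cell is split into six tetrahedra sharing
#' the cell diagonal; crossing edges are interpolated linearly, which places
#' every mesh vertex exactly on the isosurface. Face normals are unit length
#' and oriented toward the brighter (above-threshold) side. Degenerate
#' (zero-area) triangles are dropped.
#'
#' @param volume an \code{ImageVolume} (typically after
#'   \code{\link{upsampleVolume}}).
#' @param threshold iso-intensity; for a non-empty mesh it must lie strictly
#'   between the volume minimum and maximum, otherwise an empty mesh is
#'   returned with a warning.
#' @return An \code{IsoMesh} with vertices in micrometres (voxel-centre
#'   coordinate convention).
#' @export
isosurface <- function(volume, threshold) {
  stopifnot(is(volume, "ImageVolume"))
  v <- voxels(volume)
  d <- dim(v)
  sp <- voxelSpacing(volume)
  if (threshold <= min(v) || threshold >= max(v)) {
    warning("threshold outside the open intensity range: empty mesh")
    return(new("IsoMesh", vertices = matrix(0, 0, 3),
               faces = matrix(0L, 0, 3), normals = matrix(0, 0, 3),
               areas = numeric(0)))
  }
  nc <- d - 1L
  ncube <- prod(nc)
  # cube base indices (1-based corner 0)
  bi <- rep(seq_len(nc[1]), times = nc[2] * nc[3])
  bj <- rep(rep(seq_len(nc[2]), each = nc[1]), times = nc[3])
  bk <- rep(seq_len(nc[3]), each = nc[1] * nc[2])
  corner <- matrix(0, ncube, 8)
  for (c8 in 1:8) {
    off <- .cornerOffsets[c8, ]
    corner[, c8] <- v[cbind(bi + off[1], bj + off[2], bk + off[3])]
  }
  above <- corner > threshold

  # edge interpolation between two tet corners, vectorized over tets
  edgePoint <- function(ci, cj, rows) {
    va <- corner[cbind(rows, ci)]
    vb <- corner[cbind(rows, cj)]
    t <- (threshold - va) / (vb - va)
    oa <- .cornerOffsets[ci, , drop = FALSE]
    ob <- .cornerOffsets[cj, , drop = FALSE]
    base <- cbind(bi[rows], bj[rows], bk[rows]) - 1
    (base + oa[rep(1, length(rows)), ] +
       t * (ob - oa)[rep(1, length(rows)), ]) * sp
  }

  tris <- list()
  for (tt in seq_len(6)) {
    tc <- .cubeTets[tt, ] + 1L          # 4 cube-corner indices (1-based)
    tAbove <- above[, tc, drop = FALSE]
    nAbove <- rowSums(tAbove)
    # one corner separated from the other three: single triangle
    for (apex in 1:4) {
      rest <- setdiff(1:4, apex)
      # apex above, others below
      rows <- which(nAbove == 1L & tAbove[, apex])
      rows2 <- which(nAbove == 3L & !tAbove[, apex])
      for (rowSet in list(list(r = rows, apexAbove = TRUE),
                          list(r = rows2, apexAbove = FALSE))) {
        r <- rowSet$r
        if (!length(r)) next
        p1 <- edgePoint(tc[apex], tc[rest[1]], r)
        p2 <- edgePoint(tc[apex], tc[rest[2]], r)
        p3 <- edgePoint(tc[apex], tc[rest[3]], r)
        # orientation handled globally below via the above-side centroid
        apexPos <- (cbind(bi[r], bj[r], bk[r]) - 1 +
                      matrix(.cornerOffsets[tc[apex], ], length(r), 3,
                             byrow = TRUE)) * sp
        tris[[length(tris) + 1L]] <-
          list(a = p1, b = p2, c = p3, toward = apexPos,
               apexAbove = rowSet$apexAbove)
      }
    }
    # two-two split: quad cut, two triangles
    pairs <- rbind(c(1, 2), c(1, 3), c(1, 4))
    for (pp in seq_len(nrow(pairs))) {
      hi <- pairs[pp, ]
      lo <- setdiff(1:4, hi)
      rows <- which(nAbove == 2L & tAbove[, hi[1]] & tAbove[, hi[2]])
      rows2 <- which(nAbove == 2L & tAbove[, lo[1]] & tAbove[, lo[2]])
      for (rowSet in list(list(r = rows, hiC = hi, loC = lo),
                          list(r = rows2, hiC = lo, loC = hi))) {
        r <- rowSet$r
        if (!length(r)) next
        h <- rowSet$hiC; w <- rowSet$loC
        # crossing edges: h1-w1, h1-w2, h2-w1, h2-w2
        q11 <- edgePoint(tc[h[1]], tc[w[1]], r)
        q12 <- edgePoint(tc[h[1]], tc[w[2]], r)
        q21 <- edgePoint(tc[h[2]], tc[w[1]], r)
        q22 <- edgePoint(tc[h[2]], tc[w[2]], r)
        hiPos <- ((cbind(bi[r], bj[r], bk[r]) - 1 +
                     matrix(.cornerOffsets[tc[h[1]], ], length(r), 3,
                            byrow = TRUE)) +
                  (cbind(bi[r], bj[r], bk[r]) - 1 +
                     matrix(.cornerOffsets[tc[h[2]], ], length(r), 3,
                            byrow = TRUE))) / 2 * sp
        tris[[length(tris) + 1L]] <-
          list(a = q11, b = q12, c = q21, toward = hiPos, apexAbove = TRUE)
        tris[[length(tris) + 1L]] <-
          list(a = q21, b = q12, c = q22, toward = hiPos, apexAbove = TRUE)
      }
    }
  }
  if (!length(tris)) {
    return(new("IsoMesh", vertices = matrix(0, 0, 3),
               faces = matrix(0L, 0, 3), normals = matrix(0, 0, 3),
               areas = numeric(0)))
  }
  A <- do.call(rbind, lapply(tris, `[[`, "a"))
  B <- do.call(rbind, lapply(tris, `[[`, "b"))
  C <- do.call(rbind, lapply(tris, `[[`, "c"))
  TW <- do.call(rbind, lapply(tris, `[[`, "toward"))
  towardAbove <- unlist(lapply(tris, function(t)
    rep(t$apexAbove, nrow(t$a))))

  nrm <- .crossRows(B - A, C - A)
  area <- 0.5 * sqrt(rowSums(nrm^2))
  keep <- area > 1e-9 * sp^2
  A <- A[keep, , drop = FALSE]; B <- B[keep, , drop = FALSE]
  C <- C[keep, , drop = FALSE]
  nrm <- nrm[keep, , drop = FALSE]; area <- area[keep]
  TW <- TW[keep, , drop = FALSE]; towardAbove <- towardAbove[keep]
  nrm <- .normalizeRows(nrm)
  centroid <- (A + B + C) / 3
  s <- rowSums(nrm * (TW - centroid))
  flip <- ifelse(towardAbove, s < 0, s > 0)
  nrm[flip, ] <- -nrm[flip, , drop = FALSE]

  nf <- nrow(A)
  verts <- matrix(0, 3 * nf, 3)
  verts[seq(1, 3 * nf, 3), ] <- A
  verts[seq(2, 3 * nf, 3), ] <- B
  verts[seq(3, 3 * nf, 3), ] <- C
  faces <- matrix(seq_len(3 * nf), nf, 3, byrow = TRUE)
  new("IsoMesh", vertices = verts, faces = faces, normals = nrm,
      areas = area)
}

#' Axial mean surface normal per grid box
#'
#' Partitions the mesh faces into cubic boxes (by face centroid) aligned
#' with a coarse acquisition grid, and within each box computes the axial
#' mean normal: the principal eigenvector of the area-weighted axial scatter
#' matrix \eqn{\sum_i w_i n_i n_i^T} of the contained face normals. Surface
#' normals are axial data (a face's sign is arbitrary), so the scatter
#' matrix - not the arithmetic mean - is the appropriate estimator. The
#' mean resultant length Rbar is computed after aligning each normal's sign
#' with the mean, and the von Mises-Fisher concentration K follows from
#' Rbar. Boxes with fewer than \code{minFaces} faces, or concentration below
#' \code{kThreshold}, are marked not kept.
#'
#' @param mesh an \code{IsoMesh}.
#' @param boxUm box edge length in micrometres (200 matches the coarse
#'   acquisition voxel).
#' @param origin coordinates of the grid corner the boxes are anchored to;
#'   box (0,0,0) covers \code{[origin, origin + boxUm)}. To align boxes with
#'   the voxels of a coarse grid whose centres follow the package's 0-based
#'   convention, use \code{origin = rep(-boxUm/2 / ratio, 3)} style anchoring
#'   or simply \code{-nativeSpacing/2} for each axis.
#' @param kThreshold concentration threshold for the keep flag (inclusive).
#' @param minFaces minimum face count for a usable box.
#' @return A data.frame with one row per non-empty box: box indices
#'   \code{ix, iy, iz} (0-based), the axial mean normal \code{nx, ny, nz},
#'   \code{rbar}, concentration \code{kappa}, \code{nFaces}, \code{area} and
#'   logical \code{keep}.
#' @export
boxAxialNormal <- function(mesh, boxUm = 200, origin = c(0, 0, 0),
                           kThreshold = 7, minFaces = 10L) {
  stopifnot(is(mesh, "IsoMesh"))
  nf <- nrow(mesh@faces)
  empty <- data.frame(ix = integer(0), iy = integer(0), iz = integer(0),
                      nx = numeric(0), ny = numeric(0), nz = numeric(0),
                      rbar = numeric(0), kappa = numeric(0),
                      nFaces = integer(0), area = numeric(0),
                      keep = logical(0))
  if (nf == 0L) return(empty)
  cent <- (mesh@vertices[mesh@faces[, 1], , drop = FALSE] +
           mesh@vertices[mesh@faces[, 2], , drop = FALSE] +
           mesh@vertices[mesh@faces[, 3], , drop = FALSE]) / 3
  idx <- floor(sweep(cent, 2, origin) / boxUm)
  key <- paste(idx[, 1], idx[, 2], idx[, 3], sep = ",")
  groups <- split(seq_len(nf), key)
  res <- lapply(groups, function(rows) {
    nrm <- mesh@normals[rows, , drop = FALSE]
    w <- mesh@areas[rows]
    S <- crossprod(nrm * sqrt(w))       # sum_i w_i n_i n_i^T
    ev <- eigen(S, symmetric = TRUE)
    nFI <- .fixSign(ev$vectors[, 1])
    sgn <- sign(drop(nrm %*% nFI))
    sgn[sgn == 0] <- 1
    Rbar <- sqrt(sum((colSums(nrm * sgn * w))^2)) / sum(w)
    kap <- if (length(rows) >= 2L) vmfConcentration(nrm, weights = w)
           else NA_real_
    data.frame(ix = idx[rows[1], 1], iy = idx[rows[1], 2],
               iz = idx[rows[1], 3], nx = nFI[1], ny = nFI[2], nz = nFI[3],
               rbar = Rbar, kappa = kap, nFaces = length(rows),
               area = sum(w),
               keep = length(rows) >= minFaces && !is.na(kap) &&
                 kap >= kThreshold)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$ix, out$iy, out$iz), , drop = FALSE]
}

#' von Mises-Fisher concentration of (axial) surface normals
#'
#' Estimates the concentration parameter K of a 3-dimensional von
#' Mises-Fisher distribution from unit normals, after aligning the sign of
#' every normal with the axial mean direction (the principal eigenvector of
#' the weighted axial scatter matrix). Uses the closed-form approximation
#' \deqn{\hat K = \bar R (3 - \bar R^2) / (1 - \bar R^2)} from the mean
#' resultant length \eqn{\bar R}. Large K means the normals cluster tightly
#' around one orientation (a simple, single-sheet laminar geometry); K of
#' uniformly scattered normals is near zero.
#'
#' @param normals n x 3 matrix of unit vectors, n >= 2.
#' @param weights optional non-negative weights (e.g. face areas).
#' @return Estimated concentration; \code{Inf} when \eqn{\bar R = 1} within
#'   1e-12 (perfectly aligned normals).
#' @export
vmfConcentration <- function(normals, weights = NULL) {
  if (is.null(dim(normals)) || nrow(normals) < 2L)
    stop("at least 2 normals required")
  if (is.null(weights)) weights <- rep(1, nrow(normals))
  if (any(weights < 0)) stop("weights must be >= 0")
  S <- crossprod(normals * sqrt(weights))
  mu <- eigen(S, symmetric = TRUE)$vectors[, 1]
  sgn <- sign(drop(normals %*% mu))
  sgn[sgn == 0] <- 1
  Rbar <- sqrt(sum((colSums(normals * sgn * weights))^2)) / sum(weights)
  if (Rbar >= 1 - 1e-12) return(Inf)
  Rbar * (3 - Rbar^2) / (1 - Rbar^2)
}

#' Filter box summaries on concentration and face count
#'
#' Keeps the boxes whose laminar geometry is simple enough for a single
#' normal to be meaningful: concentration at least \code{kThreshold}
#' (inclusive) and at least \code{minFaces} contributing faces.
#'
#' @param summaries data.frame from \code{\link{boxAxialNormal}}.
#' @param kThreshold concentration threshold (default 7.0, inclusive).
#' @param minFaces minimum face count (default 10).
#' @return The kept subset of \code{summaries} with the keep flag refreshed.
#' @export
filterBoxes <- function(summaries, kThreshold = 7, minFaces = 10L) {
  if (nrow(summaries) == 0L) return(summaries)
  keep <- !is.na(summaries$kappa) & summaries$kappa >= kThreshold &
    summaries$nFaces >= minFaces
  out <- summaries[keep, , drop = FALSE]
  out$keep <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}
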