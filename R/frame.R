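# Cylindrical cardiac reference frame: per-voxel circumferential /
# longitudinal / radial basis around a user-supplied long axis, the four
# projected orientation angles for axial vector fields, and cuboidal ROI
# extraction in frame coordinates.

#' Build a cylindrical cardiac frame over a voxel grid
#'
#' For every voxel centre, the radial direction \code{r} is the normalized
#' rejection of (position - axisPoint) from the long-axis direction \code{l},
#' and the circumferential direction is \code{c = l x r}, giving a
#' right-handed orthonormal basis (c, l, r). Voxels lying on the axis (zero
#' rejection) are flagged undefined and excluded from angle maps.
#'
#' @param dims voxel counts per axis (length 3).
#' @param spacing voxel spacing in micrometres.
#' @param axisPoint a point on the long axis, micrometres.
#' @param axisDir long-axis direction (apex to base); need not be unit.
#' @return A \code{CardiacFrame}.
#' @export
buildFrame <- function(dims, spacing, axisPoint, axisDir = c(0, 0, 1)) {
  if (sqrt(sum(axisDir^2)) == 0) stop("'axisDir' must be nonzero")
  l <- axisDir / sqrt(sum(axisDir^2))
  dims <- as.integer(dims)
  pos <- .voxelPositions(dims, spacing)
  nvox <- prod(dims)
  P <- cbind(rep(pos$x, times = dims[2] * dims[3]),
             rep(rep(pos$y, each = dims[1]), times = dims[3]),
             rep(pos$z, each = dims[1] * dims[2]))
  D <- sweep(P, 2, axisPoint)
  along <- D %*% l
  Rej <- D - along %*% t(l)
  rlen <- sqrt(rowSums(Rej^2))
  defined <- rlen > 1e-9 * max(spacing, 1)
  Rv <- Rej / ifelse(rlen > 0, rlen, 1)
  Lv <- matrix(rep(l, each = nvox), nvox, 3)
  Cv <- .crossRows(Lv, Rv)
  Rv[!defined, ] <- NA; Cv[!defined, ] <- NA
  new("CardiacFrame",
      circumferential = array(Cv, c(dims, 3)),
      longitudinal = array(Lv, c(dims, 3)),
      radial = array(Rv, c(dims, 3)),
      defined = array(defined, dims),
      axisPoint = as.numeric(axisPoint), axisDir = l, spacing = spacing)
}

# dot products of a vector field (nvox x 3) with the frame basis
.frameDots <- function(v, frame) {
  cmat <- .flattenField(frame@circumferential)
  lmat <- .flattenField(frame@longitudinal)
  rmat <- .flattenField(frame@radial)
  list(c = rowSums(v * cmat), l = rowSums(v * lmat), r = rowSums(v * rmat))
}

.projAngle <- function(num, den) {
  # angle of the projection with components (den, num); undefined when the
  # projection is degenerate (both components ~ 0, i.e. v perpendicular to
  # the projection plane)
  a <- .fold180(.rad2deg(atan2(num, den)))
  a[sqrt(num^2 + den^2) < 1e-9] <- NA_real_
  a
}

#' Projected orientation angles of axial vectors
#'
#' The four projection angles of an axial (sign-free) unit vector within the
#' local cardiac basis (circumferential c, longitudinal l, radial r), each
#' folded into (-90, 90] degrees:
#' \describe{
#'   \item{\code{helixAngle}}{angle between the short-axis plane and the
#'     projection onto the wall-tangent (c-l) plane; the classical myocyte
#'     helix angle.}
#'   \item{\code{transverseAngleMyocyte}}{angle between the wall-tangent
#'     plane and the projection onto the short-axis (c-r) plane.}
#'   \item{\code{sheetElevation}}{angle between the short-axis plane and the
#'     projection onto the long-axis (r-l) plane.}
#'   \item{\code{sheetTransverse}}{angle between the longitudinal-radial
#'     plane and the projection onto the short-axis (r-c) plane.}
#' }
#' All four are invariant under v -> -v. Inputs may be a single length-3
#' vector with a basis list, or an n x 3 matrix with n x 3 basis matrices.
#'
#' @param v unit vector(s): length-3 or n x 3 matrix.
#' @param basis list with elements \code{c}, \code{l}, \code{r}: length-3
#'   vectors or n x 3 matrices.
#' @return Angle(s) in degrees in (-90, 90]; NA where the projection is
#'   degenerate.
#' @name projectionAngles
NULL

.basisDots <- function(v, basis) {
  if (is.null(dim(v))) v <- matrix(v, 1)
  bd <- lapply(basis[c("c", "l", "r")], function(b) {
    if (is.null(dim(b))) matrix(b, nrow(v), 3, byrow = TRUE) else b
  })
  list(c = rowSums(v * bd$c), l = rowSums(v * bd$l), r = rowSums(v * bd$r))
}

#' @rdname projectionAngles
#' @export
helixAngle <- function(v, basis) {
  d <- .basisDots(v, basis); drop(.projAngle(d$l, d$c))
}

#' @rdname projectionAngles
#' @export
transverseAngleMyocyte <- function(v, basis) {
  d <- .basisDots(v, basis); drop(.projAngle(d$r, d$c))
}

#' @rdname projectionAngles
#' @export
sheetElevation <- function(v, basis) {
  d <- .basisDots(v, basis); drop(.projAngle(d$l, d$r))
}

#' @rdname projectionAngles
#' @export
sheetTransverse <- function(v, basis) {
  d <- .basisDots(v, basis); drop(.projAngle(d$c, d$r))
}

#' All four angle maps of a vector field in a cardiac frame
#'
#' Computes per-voxel helix, myocyte-transverse, sheet-elevation and
#' sheet-transverse angles of an axial vector field. Voxels where the frame
#' is undefined (on the axis) or where a projection is degenerate are NA.
#'
#' @param vfield numeric 4D array \code{c(nx, ny, nz, 3)} of unit vectors.
#' @param frame a \code{CardiacFrame} over the same grid.
#' @return Named list of four 3D arrays (degrees in (-90, 90]):
#'   \code{helix}, \code{transverse}, \code{sheetElevation},
#'   \code{sheetTransverse}.
#' @export
angleMaps <- function(vfield, frame) {
  stopifnot(is(frame, "CardiacFrame"))
  d <- dim(vfield)[1:3]
  if (!all(d == dim(frame@defined))) stop("field/frame grid mismatch")
  v <- .flattenField(vfield)
  dd <- .frameDots(v, frame)
  shape <- function(x) array(x, d)
  list(helix = shape(.projAngle(dd$l, dd$c)),
       transverse = shape(.projAngle(dd$r, dd$c)),
       sheetElevation = shape(.projAngle(dd$l, dd$r)),
       sheetTransverse = shape(.projAngle(dd$c, dd$r)))
}

#' Cuboidal ROI specification in frame coordinates
#'
#' @param name label, e.g. "lateral", "anterior", "septal", "posterior".
#' @param thetaRange angular sector in degrees (may wrap through 360).
#' @param radiusRange endocardial and epicardial radius (micrometres).
#' @param zRange longitudinal span along the axis (micrometres).
#' @return An \code{ROISpec}.
#' @export
roiSpec <- function(name, thetaRange, radiusRange, zRange) {
  new("ROISpec", name = name, thetaRange = as.numeric(thetaRange),
      radiusRange = as.numeric(radiusRange), zRange = as.numeric(zRange))
}

#' Extract an ROI in cylindrical frame coordinates
#'
#' Selects the voxels whose cylindrical coordinates (angular position around
#' the axis, radial distance, longitudinal position) fall inside the ROI
#' cuboid, and attaches the normalized transmural depth (0 at the
#' endocardial radius, 1 at the epicardial radius).
#'
#' @param frame a \code{CardiacFrame}.
#' @param roi an \code{ROISpec}.
#' @return A list with \code{select} (logical 3D array), \code{depth}
#'   (3D array, NA outside the ROI), and \code{n} (voxel count; a count of
#'   zero sets the \code{empty} flag).
#' @export
extractROI <- function(frame, roi) {
  stopifnot(is(frame, "CardiacFrame"), is(roi, "ROISpec"))
  d <- dim(frame@defined)
  pos <- .voxelPositions(d, frame@spacing)
  nvox <- prod(d)
  P <- cbind(rep(pos$x, times = d[2] * d[3]),
             rep(rep(pos$y, each = d[1]), times = d[3]),
             rep(pos$z, each = d[1] * d[2]))
  Dp <- sweep(P, 2, frame@axisPoint)
  l <- frame@axisDir
  z <- drop(Dp %*% l)
  Rej <- Dp - z %*% t(l)
  r <- sqrt(rowSums(Rej^2))
  # angular coordinate measured from a fixed reference perpendicular to l
  ref <- if (abs(l[1]) <= abs(l[2]) && abs(l[1]) <= abs(l[3])) c(1, 0, 0)
         else if (abs(l[2]) <= abs(l[3])) c(0, 1, 0) else c(0, 0, 1)
  e1 <- ref - sum(ref * l) * l
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(l[2] * e1[3] - l[3] * e1[2],
          l[3] * e1[1] - l[1] * e1[3],
          l[1] * e1[2] - l[2] * e1[1])
  theta <- (.rad2deg(atan2(drop(Rej %*% e2), drop(Rej %*% e1)))) %% 360
  t0 <- roi@thetaRange[1] %% 360
  t1 <- roi@thetaRange[2] %% 360
  inTheta <- if (t0 <= t1) theta >= t0 & theta <= t1
             else theta >= t0 | theta <= t1
  sel <- inTheta & r >= roi@radiusRange[1] & r <= roi@radiusRange[2] &
    z >= roi@zRange[1] & z <= roi@zRange[2] & as.vector(frame@defined)
  depth <- ifelse(sel, (r - roi@radiusRange[1]) / diff(roi@radiusRange),
                  NA_real_)
  n <- sum(sel)
  if (n == 0L) warning("ROI '", roi@name, "' selected no voxels")
  list(select = array(sel, d), depth = array(depth, d), n = n)
}
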