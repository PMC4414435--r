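#' @import methods
#' @importFrom stats fft mvfft quantile median sd rnorm runif setNames splinefun
NULL

.unitTol <- 1e-6

#' Scalar 3D image volume with isotropic voxel spacing
#'
#' Container for a 3D scalar image (for example a contrast-enhanced
#' gradient-echo volume or a single diffusion-weighted channel). Voxel
#' coordinates are 0-based, positions are taken at voxel centres, and the
#' spacing is isotropic and expressed in micrometres. This single coordinate
#' convention is shared by every function in the package.
#'
#' @slot voxels numeric 3D array of intensities.
#' @slot spacing isotropic voxel spacing in micrometres.
#' @export
setClass("ImageVolume",
  representation(voxels = "array", spacing = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(dim(object@voxels)) != 3L)
      msg <- c(msg, "'voxels' must be a 3D array")
    if (length(object@spacing) != 1L || !is.finite(object@spacing) ||
        object@spacing <= 0)
      msg <- c(msg, "'spacing' must be a single positive number (micrometres)")
    if (is.null(msg)) TRUE else msg
  })

#' @param voxels numeric 3D array of intensities.
#' @param spacing isotropic voxel spacing in micrometres.
#' @return An \code{ImageVolume} object.
#' @rdname ImageVolume-class
#' @export
ImageVolume <- function(voxels, spacing) {
  new("ImageVolume", voxels = voxels, spacing = as.numeric(spacing))
}

#' Per-voxel symmetric 3x3 tensor field
#'
#' Stores the six unique components of a symmetric per-voxel tensor (either a
#' structure tensor or a diffusion tensor) in the order
#' \code{xx, yy, zz, xy, xz, yz} along the fourth array dimension.
#'
#' @slot components numeric 4D array, \code{dim = c(nx, ny, nz, 6)}.
#' @slot spacing voxel spacing in micrometres.
#' @export
setClass("TensorField",
  representation(components = "array", spacing = "numeric"),
  validity = function(object) {
    d <- dim(object@components)
    msg <- NULL
    if (length(d) != 4L || d[4] != 6L)
      msg <- c(msg, "'components' must be a 4D array with 6 components")
    if (length(object@spacing) != 1L || object@spacing <= 0)
      msg <- c(msg, "'spacing' must be a single positive number")
    if (is.null(msg)) TRUE else msg
  })

#' @param components numeric 4D array of tensor components (xx,yy,zz,xy,xz,yz).
#' @param spacing voxel spacing in micrometres.
#' @return A \code{TensorField} object.
#' @rdname TensorField-class
#' @export
TensorField <- function(components, spacing) {
  new("TensorField", components = components, spacing = as.numeric(spacing))
}

#' Per-voxel eigen-decomposition of a tensor field
#'
#' Holds sorted eigenvalues (descending along the fourth dimension) and the
#' matching orthonormal eigenvectors of a per-voxel symmetric tensor, plus the
#' convention under which eigenvectors are mapped to microstructural
#' directions:
#' \describe{
#'   \item{\code{"st"}}{structure tensor: the eigenvector of the \emph{largest}
#'     eigenvalue is the putative sheetlet normal, the smallest the putative
#'     myocyte direction.}
#'   \item{\code{"dti"}}{diffusion tensor: the eigenvector of the
#'     \emph{largest} eigenvalue is the putative myocyte direction, the
#'     smallest the putative sheetlet normal.}
#'   \item{\code{"truth"}}{generator ground truth: slots 1..3 of the vector
#'     array hold the myocyte, sheet in-plane and sheet-normal axes.}
#' }
#' Use \code{\link{putativeMyocyte}} / \code{\link{putativeNormal}} /
#' \code{\link{putativeSheet}} to extract direction fields without worrying
#' about the convention.
#'
#' @slot values numeric 4D array \code{c(nx, ny, nz, 3)}, sorted descending.
#' @slot vectors numeric 5D array \code{c(nx, ny, nz, 3, 3)}; last index picks
#'   the eigenvector (matching \code{values}), fourth its xyz components.
#' @slot spacing voxel spacing in micrometres.
#' @slot convention one of \code{"st"}, \code{"dti"}, \code{"truth"}.
#' @export
setClass("OrientationField",
  representation(values = "array", vectors = "array", spacing = "numeric",
                 convention = "character"),
  validity = function(object) {
    dv <- dim(object@values); dw <- dim(object@vectors)
    msg <- NULL
    if (length(dv) != 4L || dv[4] != 3L)
      msg <- c(msg, "'values' must be c(nx,ny,nz,3)")
    if (length(dw) != 5L || any(dw[4:5] != 3L) || !all(dw[1:3] == dv[1:3]))
      msg <- c(msg, "'vectors' must be c(nx,ny,nz,3,3) matching 'values'")
    if (!object@convention %in% c("st", "dti", "truth"))
      msg <- c(msg, "'convention' must be 'st', 'dti' or 'truth'")
    if (is.null(msg)) TRUE else msg
  })

#' Ground-truth orthonormal triad field of a phantom
#'
#' Per-voxel unit axial vectors of the generating model: myocyte direction
#' \code{m}, sheet in-plane direction \code{s} and sheet normal \code{n}.
#' The triad is orthonormal with \code{m x s = n}.
#'
#' @slot m,s,n numeric 4D arrays \code{c(nx, ny, nz, 3)} of unit vectors.
#' @slot spacing voxel spacing in micrometres.
#' @export
setClass("GroundTruth",
  representation(m = "array", s = "array", n = "array", spacing = "numeric"),
  validity = function(object) {
    msg <- NULL
    for (nm in c("m", "s", "n")) {
      d <- dim(slot(object, nm))
      if (length(d) != 4L || d[4] != 3L)
        msg <- c(msg, sprintf("'%s' must be a c(nx,ny,nz,3) array", nm))
    }
    if (is.null(msg)) {
      norm2 <- function(a) a[, , , 1]^2 + a[, , , 2]^2 + a[, , , 3]^2
      dots <- function(a, b)
        a[, , , 1] * b[, , , 1] + a[, , , 2] * b[, , , 2] + a[, , , 3] * b[, , , 3]
      if (max(abs(norm2(object@m) - 1), abs(norm2(object@s) - 1),
              abs(norm2(object@n) - 1)) > 1e-5)
        msg <- c(msg, "triad vectors must be unit length")
      if (max(abs(dots(object@m, object@s)), abs(dots(object@m, object@n)),
              abs(dots(object@s, object@n))) > 1e-5)
        msg <- c(msg, "triad must be orthogonal")
    }
    if (is.null(msg)) TRUE else msg
  })

#' Diffusion gradient scheme
#'
#' Directions and weightings of a diffusion acquisition: unit gradient
#' directions (zero rows mark b0 acquisitions), b-values in s/mm^2, and the
#' pulse timing parameters.
#'
#' @slot directions n x 3 matrix of gradient directions; b0 rows are zero.
#' @slot bvalues numeric vector of b-values (s/mm^2), one per direction.
#' @slot smallDelta diffusion gradient pulse duration (s).
#' @slot bigDelta diffusion gradient pulse separation (s).
#' @slot gamma gyromagnetic ratio (rad s^-1 T^-1).
#' @export
setClass("GradientScheme",
  representation(directions = "matrix", bvalues = "numeric",
                 smallDelta = "numeric", bigDelta = "numeric",
                 gamma = "numeric"),
  validity = function(object) {
    msg <- NULL
    g <- object@directions
    if (ncol(g) != 3L) msg <- c(msg, "'directions' must have 3 columns")
    if (length(object@bvalues) != nrow(g))
      msg <- c(msg, "one b-value per direction required")
    if (any(object@bvalues < 0)) msg <- c(msg, "b-values must be >= 0")
    nz <- object@bvalues > 0
    if (any(nz)) {
      len <- sqrt(rowSums(g[nz, , drop = FALSE]^2))
      if (any(abs(len - 1) > 1e-8))
        msg <- c(msg, "non-b0 directions must be unit length (1e-8)")
    }
    if (object@smallDelta >= object@bigDelta)
      msg <- c(msg, "pulse duration (smallDelta) must be < separation (bigDelta)")
    if (is.null(msg)) TRUE else msg
  })

#' Binary tissue mask
#'
#' Voxel-wise tissue/non-tissue classification aligned to an
#' \code{ImageVolume}, with a provenance record of the threshold and
#' morphological operations that produced it.
#'
#' @slot mask logical 3D array.
#' @slot spacing voxel spacing in micrometres.
#' @slot provenance list recording threshold fraction, reference intensity and
#'   operations applied.
#' @export
setClass("TissueMask",
  representation(mask = "array", spacing = "numeric", provenance = "list"),
  validity = function(object) {
    msg <- NULL
    if (!is.logical(object@mask) || length(dim(object@mask)) != 3L)
      msg <- c(msg, "'mask' must be a logical 3D array")
    if (is.null(msg)) TRUE else msg
  })

#' Cylindrical cardiac reference frame
#'
#' Per-voxel right-handed orthonormal basis (circumferential \code{c},
#' longitudinal \code{l}, radial \code{r}) of a cylindrical coordinate system
#' around a user-supplied left-ventricular long axis. Voxels on the axis are
#' flagged undefined.
#'
#' @slot circumferential,longitudinal,radial numeric 4D arrays
#'   \code{c(nx,ny,nz,3)} of unit basis vectors.
#' @slot defined logical 3D array; FALSE where the voxel lies on the axis.
#' @slot axisPoint point on the long axis (micrometres).
#' @slot axisDir unit direction of the long axis (apex to base).
#' @slot spacing voxel spacing in micrometres.
#' @export
setClass("CardiacFrame",
  representation(circumferential = "array", longitudinal = "array",
                 radial = "array", defined = "array",
                 axisPoint = "numeric", axisDir = "numeric",
                 spacing = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@axisPoint) != 3L || length(object@axisDir) != 3L)
      msg <- c(msg, "'axisPoint' and 'axisDir' must be length-3")
    if (abs(sqrt(sum(object@axisDir^2)) - 1) > 1e-8)
      msg <- c(msg, "'axisDir' must be unit length")
    if (is.null(msg)) TRUE else msg
  })

#' Triangulated isosurface mesh
#'
#' Triangle mesh extracted from a scalar volume, with per-face unit normals
#' oriented toward the brighter side of the surface, and per-face areas.
#'
#' @slot vertices nv x 3 matrix of vertex positions (micrometres).
#' @slot faces nf x 3 integer matrix of vertex indices (1-based).
#' @slot normals nf x 3 matrix of unit face normals.
#' @slot areas numeric vector of face areas (square micrometres).
#' @export
setClass("IsoMesh",
  representation(vertices = "matrix", faces = "matrix", normals = "matrix",
                 areas = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (ncol(object@vertices) != 3L) msg <- c(msg, "'vertices' must be n x 3")
    if (nrow(object@faces) > 0L) {
      if (ncol(object@faces) != 3L) msg <- c(msg, "'faces' must be n x 3")
      if (nrow(object@normals) != nrow(object@faces))
        msg <- c(msg, "one normal per face required")
      if (length(object@areas) != nrow(object@faces))
        msg <- c(msg, "one area per face required")
      len <- sqrt(rowSums(object@normals^2))
      if (any(abs(len - 1) > 1e-6)) msg <- c(msg, "face normals must be unit")
      if (any(object@areas <= 0)) msg <- c(msg, "face areas must be > 0")
    }
    if (is.null(msg)) TRUE else msg
  })

#' Laminar phantom specification
#'
#' Parameters of the synthetic laminar phantoms used to exercise the pipeline:
#' a stack of bright sheetlet-interstices and dark laminae whose geometry and
#' ground-truth orientation field are known exactly.
#'
#' @slot shape integer vector of 3 voxel counts.
#' @slot spacing isotropic voxel spacing (micrometres).
#' @slot laminaPeriod sheetlet + interstice repeat distance (micrometres).
#' @slot intersticeFraction fraction (0-1) of the period occupied by the
#'   bright interstice.
#' @slot geometry \code{"slab"} or \code{"annulus"}.
#' @slot helixEndo,helixEpi endocardial/epicardial helix angles in degrees
#'   (annulus geometry only).
#' @slot innerRadius,outerRadius annulus radii in micrometres.
#' @slot sheetElevation function mapping normalized transmural depth (0-1) to
#'   sheet elevation in degrees (annulus only).
#' @slot baseline,contrast dark-lamina intensity and interstice contrast
#'   amplitude (intensity units).
#' @slot noiseSigma additive Gaussian noise SD (intensity units).
#' @slot seed integer random seed for noise generation.
#' @export
setClass("PhantomSpec",
  representation(shape = "integer", spacing = "numeric",
                 laminaPeriod = "numeric", intersticeFraction = "numeric",
                 geometry = "character", helixEndo = "numeric",
                 helixEpi = "numeric", innerRadius = "numeric",
                 outerRadius = "numeric", sheetElevation = "function",
                 baseline = "numeric", contrast = "numeric",
                 noiseSigma = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (length(object@shape) != 3L || any(object@shape < 1L))
      msg <- c(msg, "'shape' must be 3 positive voxel counts")
    if (object@spacing <= 0) msg <- c(msg, "'spacing' must be > 0")
    if (object@laminaPeriod < 2 * object@spacing)
      msg <- c(msg, "laminaPeriod must be >= 2 * spacing (structure resolvable)")
    if (object@intersticeFraction <= 0 || object@intersticeFraction >= 1)
      msg <- c(msg, "intersticeFraction must be in (0, 1)")
    if (!object@geometry %in% c("slab", "annulus"))
      msg <- c(msg, "geometry must be 'slab' or 'annulus'")
    if (abs(object@helixEndo) > 90 || abs(object@helixEpi) > 90)
      msg <- c(msg, "helix angles must be within [-90, 90] degrees")
    if (object@geometry == "annulus" &&
        object@innerRadius >= object@outerRadius)
      msg <- c(msg, "innerRadius must be < outerRadius")
    if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
    if (is.null(msg)) TRUE else msg
  })

#' Cuboidal region of interest in frame coordinates
#'
#' A transmural ROI defined in the cylindrical cardiac frame: an angular
#' sector, a radial (transmural) span, and a longitudinal span.
#'
#' @slot name ROI label, e.g. \code{"lateral"} or \code{"septal"}.
#' @slot thetaRange angular sector in degrees (start, end), counter-clockwise
#'   from the frame's reference direction; may wrap through 360.
#' @slot radiusRange radial span (micrometres): endocardial then epicardial
#'   radius, used to attach normalized transmural depth.
#' @slot zRange longitudinal span (micrometres along the axis direction).
#' @export
setClass("ROISpec",
  representation(name = "character", thetaRange = "numeric",
                 radiusRange = "numeric", zRange = "numeric"),
  validity = function(object) {
    msg <- NULL
    for (nm in c("thetaRange", "radiusRange", "zRange"))
      if (length(slot(object, nm)) != 2L)
        msg <- c(msg, sprintf("'%s' must have length 2", nm))
    if (length(msg) == 0 && diff(object@radiusRange) <= 0)
      msg <- c(msg, "radiusRange must be increasing (endo < epi)")
    if (length(msg) == 0 && diff(object@zRange) <= 0)
      msg <- c(msg, "zRange must be increasing")
    if (is.null(msg)) TRUE else msg
  })

#' Monoexponential diffusion-tensor fit result
#'
#' @slot tensors fitted \code{TensorField} (mm^2/s).
#' @slot eigen \code{OrientationField} with convention \code{"dti"}.
#' @slot fa 3D array of fractional anisotropy values.
#' @slot s0 3D array of fitted/observed b0 intensities.
#' @slot flags list of logical QC arrays: \code{missing} (non-positive signal,
#'   voxel not fitted), \code{clampedNegative} (negative eigenvalue clamped to
#'   zero), \code{isotropic} (all eigenvalues equal within tolerance, the
#'   eigenvector assignment is arbitrary).
#' @export
setClass("DTIFit",
  representation(tensors = "TensorField", eigen = "OrientationField",
                 fa = "array", s0 = "array", flags = "list"))
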