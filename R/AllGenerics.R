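#' Accessors for the package's imaging containers
#'
#' Small accessor generics used instead of direct slot access:
#' \code{voxels()} returns the raw intensity array of an \code{ImageVolume},
#' \code{voxelSpacing()} the isotropic voxel spacing in micrometres,
#' \code{tensorComponents()} the 4D component array of a \code{TensorField}
#' (order xx, yy, zz, xy, xz, yz), \code{eigenValues()} /
#' \code{eigenVectors()} the sorted eigen-decomposition of an
#' \code{OrientationField}, and \code{maskArray()} the logical array of a
#' \code{TissueMask}.
#'
#' @param x an object of the corresponding class.
#' @return The underlying array or numeric value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))
#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setGeneric("tensorComponents", function(x) standardGeneric("tensorComponents"))
#' @rdname accessors
#' @export
setGeneric("eigenValues", function(x) standardGeneric("eigenValues"))
#' @rdname accessors
#' @export
setGeneric("eigenVectors", function(x) standardGeneric("eigenVectors"))
#' @rdname accessors
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))

#' Putative microstructural direction fields
#'
#' Extract the per-voxel unit axial vector field assigned to a structural
#' feature, resolving the eigenvector-to-feature mapping of the object's
#' convention. For a structure tensor the eigenvector of the largest
#' eigenvalue is the putative sheetlet normal and the smallest the putative
#' myocyte direction; for a diffusion tensor the assignment is reversed; for
#' generator ground truth the stored m/s/n axes are returned directly.
#'
#' @param x an \code{OrientationField} or \code{GroundTruth}.
#' @return A numeric 4D array \code{c(nx, ny, nz, 3)} of unit vectors.
#' @name putative
NULL

#' @rdname putative
#' @export
setGeneric("putativeMyocyte", function(x) standardGeneric("putativeMyocyte"))
#' @rdname putative
#' @export
setGeneric("putativeSheet", function(x) standardGeneric("putativeSheet"))
#' @rdname putative
#' @export
setGeneric("putativeNormal", function(x) standardGeneric("putativeNormal"))

#' @rdname accessors
#' @export
setMethod("voxels", "ImageVolume", function(x) x@voxels)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "ImageVolume", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "TensorField", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "OrientationField", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "GroundTruth", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "TissueMask", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("tensorComponents", "TensorField", function(x) x@components)
#' @rdname accessors
#' @export
setMethod("eigenValues", "OrientationField", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("eigenVectors", "OrientationField", function(x) x@vectors)
#' @rdname accessors
#' @export
setMethod("maskArray", "TissueMask", function(x) x@mask)

#' @rdname accessors
#' @export
setMethod("dim", "ImageVolume", function(x) dim(x@voxels))
#' @rdname accessors
#' @export
setMethod("dim", "TensorField", function(x) dim(x@components)[1:3])
#' @rdname accessors
#' @export
setMethod("dim", "OrientationField", function(x) dim(x@values)[1:3])
#' @rdname accessors
#' @export
setMethod("dim", "GroundTruth", function(x) dim(x@m)[1:3])
#' @rdname accessors
#' @export
setMethod("dim", "TissueMask", function(x) dim(x@mask))

.pickVector <- function(x, which) {
  v <- x@vectors[, , , , which, drop = FALSE]
  dim(v) <- dim(v)[1:4]
  v
}

#' @rdname putative
#' @export
setMethod("putativeMyocyte", "OrientationField", function(x) {
  switch(x@convention, st = .pickVector(x, 3L), dti = .pickVector(x, 1L),
         truth = .pickVector(x, 1L))
})
#' @rdname putative
#' @export
setMethod("putativeSheet", "OrientationField", function(x) .pickVector(x, 2L))
#' @rdname putative
#' @export
setMethod("putativeNormal", "OrientationField", function(x) {
  switch(x@convention, st = .pickVector(x, 1L), dti = .pickVector(x, 3L),
         truth = .pickVector(x, 3L))
})
#' @rdname putative
#' @export
setMethod("putativeMyocyte", "GroundTruth", function(x) x@m)
#' @rdname putative
#' @export
setMethod("putativeSheet", "GroundTruth", function(x) x@s)
#' @rdname putative
#' @export
setMethod("putativeNormal", "GroundTruth", function(x) x@n)

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object)
  cat(sprintf("ImageVolume: %d x %d x %d voxels at %g um\n",
              d[1], d[2], d[3], object@spacing))
  v <- object@voxels
  cat(sprintf("  intensity range [%g, %g]\n", min(v), max(v)))
})

setMethod("show", "TensorField", function(object) {
  d <- dim(object)
  cat(sprintf("TensorField: %d x %d x %d symmetric 3x3 tensors at %g um\n",
              d[1], d[2], d[3], object@spacing))
})

setMethod("show", "OrientationField", function(object) {
  d <- dim(object)
  cat(sprintf("OrientationField (%s): %d x %d x %d triads at %g um\n",
              object@convention, d[1], d[2], d[3], object@spacing))
})

setMethod("show", "GroundTruth", function(object) {
  d <- dim(object)
  cat(sprintf("GroundTruth: %d x %d x %d m/s/n triads at %g um\n",
              d[1], d[2], d[3], object@spacing))
})

setMethod("show", "GradientScheme", function(object) {
  nb0 <- sum(object@bvalues == 0)
  cat(sprintf(paste0("GradientScheme: %d diffusion directions + %d b0, ",
                     "b up to %g s/mm^2\n  delta = %g ms, Delta = %g ms\n"),
              sum(object@bvalues > 0), nb0, max(object@bvalues),
              object@smallDelta * 1e3, object@bigDelta * 1e3))
})

setMethod("show", "TissueMask", function(object) {
  d <- dim(object)
  cat(sprintf("TissueMask: %d x %d x %d, %d tissue voxels (%.1f%%)\n",
              d[1], d[2], d[3], sum(object@mask),
              100 * mean(object@mask)))
})

setMethod("show", "IsoMesh", function(object) {
  cat(sprintf("IsoMesh: %d vertices, %d faces, total area %.4g um^2\n",
              nrow(object@vertices), nrow(object@faces), sum(object@areas)))
})

setMethod("show", "CardiacFrame", function(object) {
  d <- dim(object@defined)
  cat(sprintf("CardiacFrame: %d x %d x %d, axis through (%g, %g, %g) um\n",
              d[1], d[2], d[3], object@axisPoint[1], object@axisPoint[2],
              object@axisPoint[3]))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(paste0("PhantomSpec (%s): %d x %d x %d voxels at %g um, ",
                     "lamina period %g um\n"),
              object@geometry, object@shape[1], object@shape[2],
              object@shape[3], object@spacing, object@laminaPeriod))
})

setMethod("show", "DTIFit", function(object) {
  d <- dim(object@tensors)
  cat(sprintf("DTIFit: %d x %d x %d tensors, median FA %.3f\n",
              d[1], d[2], d[3], median(object@fa, na.rm = TRUE)))
})
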