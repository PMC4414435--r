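# File interfaces: NIfTI volumes and vector/tensor fields (micrometre
# spacing carried in the header), FSL-style bvec/bval text files, ASCII PLY
# meshes, and YAML phantom/pipeline configuration.

#' Read and write volumes as NIfTI
#'
#' Volumes are stored with the voxel spacing (micrometres) in the NIfTI
#' pixdim; vector and tensor fields use a 4D NIfTI whose fourth dimension
#' holds components.
#'
#' @param path file path (\code{.nii} or \code{.nii.gz}).
#' @param volume an \code{ImageVolume}.
#' @return \code{readVolume} returns an \code{ImageVolume}.
#' @name volumeIO
NULL

#' @rdname volumeIO
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("expected a 3D NIfTI volume")
  a <- array(as.numeric(img), dim(img))
  ImageVolume(a, RNifti::pixdim(img)[1])
}

#' @rdname volumeIO
#' @export
writeVolume <- function(volume, path) {
  stopifnot(is(volume, "ImageVolume"))
  img <- RNifti::asNifti(voxels(volume))
  RNifti::pixdim(img) <- rep(voxelSpacing(volume), 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @param field 4D numeric array (components along the last dimension).
#' @param spacing voxel spacing in micrometres.
#' @rdname volumeIO
#' @export
writeFieldNifti <- function(field, spacing, path) {
  img <- RNifti::asNifti(field)
  RNifti::pixdim(img) <- c(rep(spacing, 3), 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname volumeIO
#' @export
readFieldNifti <- function(path) {
  img <- RNifti::readNifti(path)
  list(field = array(as.numeric(img), dim(img)),
       spacing = RNifti::pixdim(img)[1])
}

#' Read and write FSL-style gradient tables
#'
#' \code{bvec} holds three whitespace-separated rows (x, y, z components,
#' one column per acquisition); \code{bval} one row of b-values.
#'
#' @param scheme a \code{GradientScheme}.
#' @param bvecPath,bvalPath file paths.
#' @param smallDelta,bigDelta,gamma timing parameters to attach on read
#'   (not stored in the FSL format).
#' @return \code{readGradientScheme} returns a \code{GradientScheme}.
#' @name gradientIO
NULL

#' @rdname gradientIO
#' @export
writeGradientScheme <- function(scheme, bvecPath, bvalPath) {
  stopifnot(is(scheme, "GradientScheme"))
  n <- nrow(scheme@directions)
  writeLines(vapply(1:3, function(cc)
    paste(sprintf("%.16g", scheme@directions[, cc]), collapse = " "),
    character(1)), bvecPath)
  writeLines(paste(sprintf("%.16g", scheme@bvalues), collapse = " "),
             bvalPath)
  invisible(c(bvecPath, bvalPath))
}

#' @rdname gradientIO
#' @export
readGradientScheme <- function(bvecPath, bvalPath, smallDelta = 3.6e-3,
                               bigDelta = 11.5e-3,
                               gamma = 2 * pi * 42.58e6) {
  bvec <- as.matrix(utils::read.table(bvecPath))
  bval <- as.numeric(scan(bvalPath, quiet = TRUE))
  gradientScheme(directions = t(unname(bvec)), bvalues = bval,
                 smallDelta = smallDelta, bigDelta = bigDelta, gamma = gamma)
}

#' Write a mesh as ASCII PLY
#'
#' @param mesh an \code{IsoMesh}.
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeMeshPLY <- function(mesh, path) {
  stopifnot(is(mesh, "IsoMesh"))
  con <- file(path, "w")
  on.exit(close(con))
  nv <- nrow(mesh@vertices); nf <- nrow(mesh@faces)
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nv),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nf),
               "property list uchar int vertex_indices", "end_header"), con)
  if (nv) utils::write.table(format(mesh@vertices, trim = TRUE), con,
                      row.names = FALSE, col.names = FALSE, quote = FALSE)
  if (nf) utils::write.table(cbind(3L, mesh@faces - 1L), con, row.names = FALSE,
                      col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Phantom specification from a YAML list
#'
#' @param config named list (e.g. parsed from YAML) of
#'   \code{\link{phantomSpec}} arguments; \code{sheetElevation} may be given
#'   as a constant in degrees.
#' @return A \code{PhantomSpec}.
#' @export
phantomSpecFromList <- function(config) {
  if (!is.null(config$sheetElevation) && is.numeric(config$sheetElevation)) {
    const <- config$sheetElevation
    config$sheetElevation <- function(depth) rep(const, length(depth))
  }
  do.call(phantomSpec, config)
}
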