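# Diffusion-tensor reconstruction: the b-value relation, the free-water
# displacement check, the monoexponential log-linear tensor fit, and
# fractional anisotropy.

#' Diffusion weighting (b-value) of a monopolar pulse pair
#'
#' \deqn{b = \gamma^2 \delta^2 (\Delta - \delta/3) |g|^2}
#' where \eqn{\gamma} is the gyromagnetic ratio, \eqn{\delta} the diffusion
#' gradient pulse duration, \eqn{\Delta} the pulse separation and \eqn{|g|}
#' the gradient amplitude. For protons \eqn{\gamma/2\pi} is commonly quoted
#' as 42 MHz/T; the formula needs angular units, so the default is
#' \eqn{\gamma = 2\pi \cdot 42.58\times 10^6} rad s^-1 T^-1.
#'
#' @param gamma gyromagnetic ratio (rad s^-1 T^-1).
#' @param delta gradient pulse duration (s).
#' @param Delta gradient pulse separation (s); must exceed \code{delta}.
#' @param gMag gradient amplitude (T/mm).
#' @return b-value in s/mm^2.
#' @export
bValue <- function(gamma = 2 * pi * 42.58e6, delta, Delta, gMag) {
  if (any(delta <= 0) || any(delta >= Delta))
    stop("need 0 < delta < Delta")
  if (any(gMag < 0)) stop("gradient amplitude must be >= 0")
  gamma^2 * delta^2 * (Delta - delta / 3) * gMag^2
}

#' Gradient amplitude achieving a target b-value
#'
#' Inverts the b-value relation for \eqn{|g|}.
#'
#' @inheritParams bValue
#' @param b target b-value (s/mm^2).
#' @return Gradient amplitude in T/mm.
#' @export
gradientForB <- function(b, gamma = 2 * pi * 42.58e6, delta, Delta) {
  if (any(b < 0)) stop("b must be >= 0")
  sqrt(b / (gamma^2 * delta^2 * (Delta - delta / 3)))
}

#' Free-diffusion RMS displacement
#'
#' One-dimensional root-mean-square displacement \eqn{\sqrt{2 D \Delta}} of a
#' molecule with diffusivity D over the diffusion time \eqn{\Delta}, in
#' micrometres. For free water at 20 C (D about 2.3e-3 mm^2/s) and
#' \eqn{\Delta} = 11.5 ms this is about 7 um, which bounds the length scale a
#' diffusion acquisition actually probes.
#'
#' @param D diffusivity (mm^2/s), positive.
#' @param Delta diffusion time (s), non-negative.
#' @return Displacement in micrometres.
#' @export
rmsDisplacement <- function(D, Delta) {
  if (any(D <= 0)) stop("diffusivity must be > 0")
  if (any(Delta < 0)) stop("diffusion time must be >= 0")
  sqrt(2 * D * Delta) * 1e3
}

#' Monoexponential diffusion-tensor fit
#'
#' Per voxel, solves \eqn{\ln(S_k/S_0) = -b_k \, g_k^T D g_k} for the six
#' unique tensor components by linear least squares over all diffusion
#' directions, then eigen-decomposes the tensor. Eigenvalues are sorted
#' descending; under the DTI convention the eigenvector of the largest
#' eigenvalue is the putative myocyte direction and that of the smallest the
#' putative sheetlet normal. The fit is exact on noiseless monoexponential
#' data. Voxels with any non-positive signal are flagged missing and not
#' fitted; negative eigenvalues arising from noisy fits are clamped to zero
#' with a QC flag; voxels whose eigenvalues are all equal within 1e-6
#' relative are flagged isotropic (arbitrary eigenvectors).
#'
#' @param dwi 4D array \code{c(nx, ny, nz, nDirections)} of signals, ordered
#'   as the rows of the scheme.
#' @param scheme a \code{GradientScheme} with at least 6 non-collinear
#'   diffusion directions and at least one b0 entry.
#' @return A \code{DTIFit}.
#' @export
fitTensor <- function(dwi, scheme) {
  stopifnot(is(scheme, "GradientScheme"))
  d4 <- dim(dwi)
  if (length(d4) != 4L || d4[4] != nrow(scheme@directions))
    stop("dwi must be c(nx,ny,nz,nDirections) matching the scheme")
  d <- d4[1:3]
  isB0 <- scheme@bvalues == 0
  if (!any(isB0)) stop("scheme must include a b0 entry")
  if (sum(!isB0) < 6L) stop("at least 6 diffusion directions required")
  g <- scheme@directions[!isB0, , drop = FALSE]
  b <- scheme@bvalues[!isB0]
  X <- b * cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
                 2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3],
                 2 * g[, 2] * g[, 3])
  qrX <- qr(X)
  if (qrX$rank < 6L)
    stop("gradient directions are collinear: design matrix is singular")

  nvox <- prod(d)
  S <- matrix(dwi, nvox, d4[4])
  s0 <- rowMeans(S[, isB0, drop = FALSE])
  Sd <- S[, !isB0, drop = FALSE]
  missing <- s0 <= 0 | apply(Sd <= 0, 1, any)
  Y <- matrix(0, sum(!isB0), nvox)
  ok <- !missing
  if (any(ok))
    Y[, ok] <- -t(log(Sd[ok, , drop = FALSE] / s0[ok]))
  coefs <- qr.coef(qrX, Y)              # 6 x nvox: xx,yy,zz,xy,xz,yz
  coefs[, missing] <- NA_real_

  comp <- array(t(coefs), c(d, 6))
  compFit <- comp
  compFit[is.na(compFit)] <- 0          # placeholder for flagged voxels
  tensors <- TensorField(compFit, 1)    # grid spacing not carried by raw arrays
  e <- .eigenField(compFit)
  clamped <- apply(e$values < 0, 1, any) & !missing
  e$values[e$values < 0] <- 0
  vmax <- pmax(e$values[, 1], 1e-300)
  iso <- (e$values[, 1] - e$values[, 3]) / vmax < 1e-6 & !missing
  eigenF <- new("OrientationField",
                values = array(e$values, c(d, 3)),
                vectors = array(e$vectors, c(d, 3, 3)),
                spacing = 1, convention = "dti")
  fa <- fractionalAnisotropy(e$values)
  fa[missing] <- NA_real_
  new("DTIFit", tensors = tensors, eigen = eigenF,
      fa = array(fa, d), s0 = array(s0, d),
      flags = list(missing = array(missing, d),
                   clampedNegative = array(clamped, d),
                   isotropic = array(iso, d)))
}

#' Fractional anisotropy
#'
#' Standard rotation-invariant anisotropy index of three non-negative
#' eigenvalues: 0 for isotropic tensors, 1 in the limit of a single nonzero
#' eigenvalue.
#'
#' @param eigvals numeric vector of 3 eigenvalues, or an n x 3 matrix / 4D
#'   array with eigenvalues along the last dimension.
#' @return FA values in [0, 1]; \code{NA} where all eigenvalues are zero.
#' @export
fractionalAnisotropy <- function(eigvals) {
  if (is.null(dim(eigvals))) eigvals <- matrix(eigvals, 1)
  d <- dim(eigvals)
  m <- if (length(d) > 2) matrix(eigvals, prod(d[-length(d)]), d[length(d)])
       else eigvals
  if (any(m < -1e-12, na.rm = TRUE)) stop("eigenvalues must be >= 0")
  mb <- rowMeans(m)
  num <- rowSums((m - mb)^2)
  den <- rowSums(m^2)
  fa <- sqrt(1.5 * num / den)
  fa[den == 0] <- NA_real_
  if (length(d) > 2) array(fa, d[-length(d)]) else drop(fa)
}
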