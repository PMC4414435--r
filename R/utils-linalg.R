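# Vectorized small-linear-algebra helpers shared across modules.

.normalizeRows <- function(m) {
  len <- sqrt(rowSums(m^2))
  m / len
}

.crossRows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# Deterministic sign convention for an (axial) eigenvector: the
# largest-magnitude component is made positive; ties broken by the first
# component attaining the maximum magnitude.
.fixSign <- function(v) {
  i <- which.max(abs(v))
  if (v[i] < 0) -v else v
}

# Flatten a c(nx,ny,nz,k) array to an (nvox x k) matrix and back.
.flattenField <- function(a) {
  d <- dim(a)
  dim(a) <- c(prod(d[1:3]), d[4])
  a
}

.unflattenField <- function(m, d3) {
  dim(m) <- c(d3, ncol(m))
  m
}

# Eigen-decomposition of a per-voxel symmetric tensor field.
# comp: c(nx,ny,nz,6) in xx,yy,zz,xy,xz,yz order. Returns values (nvox x 3,
# descending) and vectors (nvox x 3 x 3). Non-finite tensors raise an error.
.eigenField <- function(comp) {
  d <- dim(comp)[1:3]
  m <- .flattenField(comp)
  if (!all(is.finite(m))) stop("non-finite tensor components")
  nvox <- nrow(m)
  values <- matrix(NA_real_, nvox, 3)
  vectors <- array(NA_real_, c(nvox, 3, 3))
  Tm <- matrix(0, 3, 3)
  for (i in seq_len(nvox)) {
    Tm[1, 1] <- m[i, 1]; Tm[2, 2] <- m[i, 2]; Tm[3, 3] <- m[i, 3]
    Tm[1, 2] <- Tm[2, 1] <- m[i, 4]
    Tm[1, 3] <- Tm[3, 1] <- m[i, 5]
    Tm[2, 3] <- Tm[3, 2] <- m[i, 6]
    e <- eigen(Tm, symmetric = TRUE)      # eigenvalues already descending
    values[i, ] <- e$values
    for (k in 1:3) vectors[i, , k] <- .fixSign(e$vectors[, k])
  }
  list(values = values, vectors = vectors, dims = d)
}

# Build an OrientationField from a TensorField under a naming convention.
.orientationFromTensors <- function(tf, convention) {
  e <- .eigenField(tf@components)
  d <- e$dims
  new("OrientationField",
      values = array(e$values, c(d, 3)),
      vectors = array(e$vectors, c(d, 3, 3)),
      spacing = tf@spacing, convention = convention)
}

# Quadratic form g' T g over a component field (xx,yy,zz,xy,xz,yz).
.quadForm <- function(comp, g) {
  comp[, , , 1] * g[1]^2 + comp[, , , 2] * g[2]^2 + comp[, , , 3] * g[3]^2 +
    2 * (comp[, , , 4] * g[1] * g[2] + comp[, , , 5] * g[1] * g[3] +
           comp[, , , 6] * g[2] * g[3])
}

# Voxel-centre positions (micrometres, 0-based indices) of a grid.
.voxelPositions <- function(dims, spacing) {
  list(x = (seq_len(dims[1]) - 1) * spacing,
       y = (seq_len(dims[2]) - 1) * spacing,
       z = (seq_len(dims[3]) - 1) * spacing)
}

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

# Fold an angle in degrees into (-90, 90] exploiting 180-degree periodicity.
.fold180 <- function(a) {
  f <- ((a + 90) %% 180) - 90
  ifelse(f == -90, 90, f)
}
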