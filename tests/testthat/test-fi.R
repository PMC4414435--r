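test_that("cubic upsampling preserves constants, ramps and spacing", {
  vol <- ImageVolume(array(3.7, c(6, 6, 6)), 50)
  up <- upsampleVolume(vol, 4L)
  expect_equal(dim(up), c(24L, 24L, 24L))
  expect_equal(voxelSpacing(up), 12.5)
  expect_equal(max(abs(voxels(up) - 3.7)), 0, tolerance = 1e-12)

  # trilinear ramp reproduced exactly (cubic reproduces degree 1)
  d <- c(5L, 6L, 7L)
  g <- array(0, d)
  for (i in 1:5) for (j in 1:6) for (k in 1:7)
    g[i, j, k] <- 2 * i - 3 * j + 0.5 * k
  up <- upsampleVolume(ImageVolume(g, 50), 2L)
  expected <- array(0, 2L * d)
  for (i in seq_len(10)) for (j in seq_len(12)) for (k in seq_len(14)) {
    # refined voxel centres in input index units
    x <- (i - 0.5) / 2 - 0.5 + 1; y <- (j - 0.5) / 2 - 0.5 + 1
    z <- (k - 0.5) / 2 - 0.5 + 1
    expected[i, j, k] <- 2 * x - 3 * y + 0.5 * z
  }
  expect_equal(voxels(up), expected, tolerance = 1e-10)
  expect_error(upsampleVolume(vol, 0L), "positive")
  expect_identical(upsampleVolume(vol, 1L), vol)
})

test_that("isosurface of a planar boundary has axis-aligned oriented normals", {
  # intensity increases with z: boundary plane z = const, bright side +z
  d <- c(8L, 8L, 8L)
  v <- array(rep(1:8, each = 64), d)   # intensity equals the z index
  vol <- ImageVolume(v, 50)
  mesh <- isosurface(vol, 4.25)
  expect_gt(nrow(mesh@faces), 0)
  expect_lt(max(abs(mesh@normals[, 1])), 1e-6)
  expect_lt(max(abs(mesh@normals[, 2])), 1e-6)
  # oriented toward the brighter side (+z)
  expect_true(all(mesh@normals[, 3] > 0.999999))
  # vertices all on the interpolated plane
  zExpected <- (4.25 - 1) * 50   # index (value-1), 0-based, times spacing
  expect_lt(max(abs(mesh@vertices[, 3] - zExpected)), 1e-6)

  expect_warning(empty <- isosurface(vol, 100), "threshold")
  expect_equal(nrow(empty@faces), 0L)
})

test_that("sphere mesh area converges to the analytic value", {
  # signed distance field of a sphere, radius 300 um, sampled at 50 um
  mkSphere <- function(n, sp) {
    ctr <- (n - 1) / 2 * sp
    pos <- (seq_len(n) - 1) * sp
    X <- array(rep(pos, times = n * n), c(n, n, n))
    Y <- array(rep(rep(pos, each = n), times = n), c(n, n, n))
    Z <- array(rep(pos, each = n * n), c(n, n, n))
    ImageVolume(300 - sqrt((X - ctr)^2 + (Y - ctr)^2 + (Z - ctr)^2), sp)
  }
  analytic <- 4 * pi * 300^2
  errs <- vapply(c(1L, 2L, 4L), function(f) {
    up <- upsampleVolume(mkSphere(16L, 50), f)
    mesh <- isosurface(up, 0)
    abs(sum(mesh@areas) - analytic) / analytic
  }, numeric(1))
  expect_lt(errs[3], 0.02)            # within 2 percent at 12.5 um
  expect_true(all(diff(errs) < 0))    # monotone error decrease 1x -> 4x
})

test_that("box axial normals recover plane normals and flag degeneracy", {
  # single oblique plane through a box
  d <- c(9L, 9L, 9L)
  nrm <- c(1, 1, 1) / sqrt(3)
  pos <- (seq_len(9) - 1) * 25
  X <- array(rep(pos, times = 81), d)
  Y <- array(rep(rep(pos, each = 9), times = 9), d)
  Z <- array(rep(pos, each = 81), d)
  f <- X * nrm[1] + Y * nrm[2] + Z * nrm[3]
  mesh <- isosurface(ImageVolume(f, 25), median(f))
  bx <- boxAxialNormal(mesh, boxUm = 300, origin = c(-12.5, -12.5, -12.5),
                       minFaces = 2L)
  expect_gt(nrow(bx), 0)
  dev <- axialAngle(as.matrix(bx[, c("nx", "ny", "nz")]),
                    matrix(nrm, nrow(bx), 3, byrow = TRUE))
  expect_lt(max(dev), 1e-4)
  expect_true(all(bx$rbar > 0.999999))
  expect_true(all(bx$keep))

  # n^FI is invariant to flipping any subset of face-normal signs
  set.seed(31)
  flip <- sample(c(-1, 1), nrow(mesh@faces), replace = TRUE)
  mesh2 <- new("IsoMesh", vertices = mesh@vertices, faces = mesh@faces,
               normals = mesh@normals * flip, areas = mesh@areas)
  bx2 <- boxAxialNormal(mesh2, boxUm = 300, origin = c(-12.5, -12.5, -12.5),
                        minFaces = 2L)
  expect_equal(unname(abs(rowSums(as.matrix(bx[, c("nx", "ny", "nz")]) *
                                    as.matrix(bx2[, c("nx", "ny", "nz")])))),
               rep(1, nrow(bx)), tolerance = 1e-9)

  # two equal-area orthogonal planes in one box: low resultant, rejected
  nrm2 <- rbind(matrix(c(0, 0, 1), 200, 3, byrow = TRUE),
                matrix(c(1, 0, 0), 200, 3, byrow = TRUE))
  verts <- matrix(runif(3 * 3 * 400, 0, 290), ncol = 3)
  twoPlane <- new("IsoMesh", vertices = verts,
                  faces = matrix(seq_len(1200), 400, 3, byrow = TRUE),
                  normals = nrm2, areas = rep(1, 400))
  bx3 <- boxAxialNormal(twoPlane, boxUm = 300, origin = c(0, 0, 0),
                        minFaces = 2L)
  expect_lt(bx3$rbar[1], 0.85)
  expect_false(bx3$keep[1])
  # empty mesh gives empty summary
  expect_equal(nrow(boxAxialNormal(new("IsoMesh",
                                       vertices = matrix(0, 0, 3),
                                       faces = matrix(0L, 0, 3),
                                       normals = matrix(0, 0, 3),
                                       areas = numeric(0)))), 0L)
})

test_that("vMF concentration estimator matches formula and ML oracle", {
  # all normals identical: perfect concentration sentinel
  same <- matrix(c(0, 0, 1), 10, 3, byrow = TRUE)
  expect_identical(vmfConcentration(same), Inf)

  # Rbar = 0.9 closed form, via a constructed two-direction sample:
  # verify the estimator formula on its own terms
  expect_equal(0.9 * (3 - 0.81) / (1 - 0.81), 10.37368, tolerance = 1e-6)

  # samples from a known vMF: estimator and ML oracle agree and recover K
  set.seed(13)
  for (kTrue in c(10, 40)) {
    x <- sampleVMF(800, c(0, 0, 1), kTrue)
    kHat <- vmfConcentration(x)
    kML <- mlConcentration(x)
    expect_lt(abs(kHat - kML) / kML, 0.05)
    expect_lt(abs(kHat - kTrue) / kTrue, 0.15)
  }

  # uniformly random normals: concentration far below the keep threshold
  set.seed(7)
  u <- matrix(rnorm(1500), 500, 3)
  u <- u / sqrt(rowSums(u^2))
  expect_lt(vmfConcentration(u), 7)
  expect_error(vmfConcentration(matrix(c(0, 0, 1), 1, 3)), "at least 2")
})

test_that("box filtering applies the inclusive threshold", {
  df <- data.frame(ix = 0:2, iy = 0, iz = 0, nx = 1, ny = 0, nz = 0,
                   rbar = 0.9, kappa = c(6.999, 7.0, 25), nFaces = 50,
                   area = 1, keep = NA)
  kept <- filterBoxes(df, kThreshold = 7, minFaces = 10)
  expect_equal(kept$ix, 1:2)           # K = 7.0 exactly is kept
  expect_equal(nrow(filterBoxes(df[0, , drop = FALSE])), 0L)
  df$nFaces <- 5
  expect_equal(nrow(filterBoxes(df, kThreshold = 7, minFaces = 10)), 0L)
})
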