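test_that("derivative templates are exact on their polynomial classes", {
  # linear ramp: both widths exact in the interior
  for (w in c(3, 5)) {
    k <- derivativeKernel(w)
    f <- 2.5 * (0:19)
    h <- (w - 1) / 2
    interior <- (h + 1):(20 - h)
    g <- vapply(interior, function(i)
      sum(k * f[i + (-h:h)]), numeric(1))
    expect_equal(g, rep(2.5, length(interior)), tolerance = 1e-12)
    expect_equal(sum(k), 0)
    expect_equal(k, -rev(k))   # antisymmetry
  }
  # cubic polynomial: width 5 exact, width 3 not (symbolic derivative oracle)
  x <- 0:19
  f <- x^3 - 2 * x^2 + 3
  dfExact <- 3 * x^2 - 4 * x
  g3 <- vapply(3:18, function(i) sum(derivativeKernel(3) * f[i + (-1:1)]),
               numeric(1))
  g5 <- vapply(3:18, function(i) sum(derivativeKernel(5) * f[i + (-2:2)]),
               numeric(1))
  expect_equal(g5, dfExact[3:18], tolerance = 1e-10)
  expect_gt(max(abs(g3 - dfExact[3:18])), 0.5)
  expect_error(derivativeKernel(4), "3 or 5")
})

test_that("structure tensor vanishes on constants and is axis-pure on ramps", {
  vol <- ImageVolume(array(7, c(8, 8, 8)), 50)
  tf <- computeStructureTensor(vol, STConfig(3, 3, 0))
  expect_lt(max(abs(tensorComponents(tf))), 1e-18)

  ramp <- ImageVolume(array(rep(1:8, times = 64), c(8, 8, 8)) * 3, 50)
  tf <- computeStructureTensor(ramp, STConfig(3, 3, 0))
  comp <- tensorComponents(tf)
  interior <- 2:7
  expect_equal(comp[interior, interior, interior, 1],
               array((3 / 50)^2, c(6, 6, 6)), tolerance = 1e-10)
  expect_lt(max(abs(comp[interior, interior, interior, 2:6])), 1e-16)
})

test_that("FFT convolution agrees with the direct spatial-domain oracle", {
  set.seed(11)
  vol <- array(runif(6 * 7 * 8), c(6, 7, 8))
  for (axis in 1:3) for (w in c(3, 5)) {
    k <- derivativeKernel(w)
    fftRes <- myolam:::.applyTemplateFFT(vol, k, axis)
    direct <- directApplyTemplate(vol, k, axis)
    expect_equal(fftRes, direct, tolerance = 1e-8)
  }
})

test_that("binomial smoothing preserves DC, trace, and matches dense oracle", {
  # constant field unchanged at half resolution
  comp <- array(0, c(8, 8, 8, 6))
  comp[, , , 1] <- 3; comp[, , , 4] <- -1
  tf <- TensorField(comp, 50)
  sm <- binomialSmoothDownsample(tf, 3)
  expect_equal(dim(sm), c(4L, 4L, 4L))
  expect_equal(voxelSpacing(sm), 100)
  expect_equal(tensorComponents(sm)[, , , 1], array(3, c(4, 4, 4)),
               tolerance = 1e-12)
  expect_equal(tensorComponents(sm)[, , , 4], array(-1, c(4, 4, 4)),
               tolerance = 1e-12)

  # random field: smoothed components match a dense convolution oracle
  set.seed(4)
  comp <- array(rnorm(8^3 * 6), c(8, 8, 8, 6))
  tf <- TensorField(comp, 50)
  sm <- binomialSmoothDownsample(tf, 3)
  k <- binomialKernel(3)
  oracle <- directApplyTemplate(directApplyTemplate(
    directApplyTemplate(comp[, , , 2], k, 1), k, 2), k, 3)
  keep <- seq(1, 8, 2)
  expect_equal(tensorComponents(sm)[, , , 2], oracle[keep, keep, keep],
               tolerance = 1e-8)

  # mean trace preserved by smoothing (weights sum to 1, linear operation)
  trFine <- comp[, , , 1] + comp[, , , 2] + comp[, , , 3]
  smTr <- tensorComponents(sm)
  trOracle <- directApplyTemplate(directApplyTemplate(
    directApplyTemplate(trFine, k, 1), k, 2), k, 3)[keep, keep, keep]
  expect_equal(smTr[, , , 1] + smTr[, , , 2] + smTr[, , , 3], trOracle,
               tolerance = 1e-10)
  expect_error(binomialSmoothDownsample(TensorField(array(1, c(2, 8, 8, 6)),
                                                    50), 3), "at least")
})

test_that("eigenanalysis sorts, orients and assigns axes correctly", {
  comp <- array(0, c(2, 2, 2, 6))
  comp[, , , 1] <- 3; comp[, , , 2] <- 2; comp[, , , 3] <- 1
  res <- stEigenanalysis(TensorField(comp, 50))
  expect_equal(eigenValues(res)[1, 1, 1, ], c(3, 2, 1))
  expect_equal(eigenVectors(res)[1, 1, 1, , 1], c(1, 0, 0))
  # ST convention: largest eigenvalue's vector is the putative normal
  expect_equal(putativeNormal(res)[1, 1, 1, ], c(1, 0, 0))
  expect_equal(putativeMyocyte(res)[1, 1, 1, ], c(0, 0, 1))
  # orthonormality
  V <- eigenVectors(res)[1, 1, 1, , ]
  expect_equal(crossprod(V), diag(3), tolerance = 1e-12)
  comp[1, 1, 1, 1] <- NaN
  expect_error(stEigenanalysis(TensorField(comp, 50)), "non-finite")
})

test_that("noiseless slab: recovered normal within 3 degrees, myocyte in plane", {
  nrm <- c(1, 2, 2) / 3
  ph <- makeSlabPhantom(phantomSpec(shape = c(32L, 32L, 32L)), normal = nrm)
  st <- structureTensorAnalysis(ph$volume, STConfig(3, 3, 2))
  nv <- prod(dim(st$eigen))
  dev <- axialAngle(flatField(putativeNormal(st$eigen)),
                    constantField(dim(st$eigen), nrm))
  expect_lt(sortingSummary(dev)$median, 3)
  offPlane <- 90 - axialAngle(flatField(putativeMyocyte(st$eigen)),
                              constantField(dim(st$eigen), nrm))
  expect_lt(sortingSummary(offPlane)$median, 3)
})

test_that("structure tensor is equivariant under 90-degree grid rotation", {
  set.seed(21)
  v <- array(runif(8^3), c(8, 8, 8))
  # rotate volume 90 degrees about x: (x,y,z) -> (x, -z, y) maps index
  # arrays by permutation and reversal
  vr <- aperm(v, c(1, 3, 2))[, , 8:1]
  tf <- computeStructureTensor(ImageVolume(v, 50), STConfig(3, 3, 0))
  tfr <- computeStructureTensor(ImageVolume(vr, 50), STConfig(3, 3, 0))
  c0 <- tensorComponents(tf); c1 <- tensorComponents(tfr)
  # gradient components transform as (gx, gy, gz) -> (gx, -gz, gy)
  expect_equal(c1[, , , 1], aperm(c0[, , , 1], c(1, 3, 2))[, , 8:1],
               tolerance = 1e-12)                       # xx
  expect_equal(c1[, , , 2], aperm(c0[, , , 3], c(1, 3, 2))[, , 8:1],
               tolerance = 1e-12)                       # yy <- zz
  expect_equal(c1[, , , 4], aperm(c0[, , , 5], c(1, 3, 2))[, , 8:1],
               tolerance = 1e-12)                       # x'y' <- xz
  expect_equal(c1[, , , 5], -aperm(c0[, , , 4], c(1, 3, 2))[, , 8:1],
               tolerance = 1e-12)                       # x'z' <- -xy
})

test_that("eigenvalue ratio maps pairs to percentages with flagged zeros", {
  expect_equal(eigenvalueRatio(2, 2), 100)
  expect_equal(eigenvalueRatio(0, 2), 0)
  expect_equal(eigenvalueRatio(1, 2), 50)
  expect_true(is.na(eigenvalueRatio(0, 0)))
  expect_error(eigenvalueRatio(3, 2), "exceed")
  expect_equal(eigenvalueRatio(c(1, 3), c(4, 4)), c(25, 75))
})

test_that("kernel-support bookkeeping matches the resolution cascade", {
  expect_identical(effectiveSupportWidth(3, 3, 0), 3L)
  expect_identical(effectiveSupportWidth(3, 3, 1), 5L)
  expect_identical(effectiveSupportWidth(5, 5, 1), 9L)
})
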