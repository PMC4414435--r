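test_that("b-value relation scales and inverts correctly", {
  expect_equal(bValue(delta = 3.6e-3, Delta = 11.5e-3, gMag = 0), 0)
  b1 <- bValue(delta = 3.6e-3, Delta = 11.5e-3, gMag = 1e-4)
  b2 <- bValue(delta = 3.6e-3, Delta = 11.5e-3, gMag = 2e-4)
  expect_equal(b2 / b1, 4, tolerance = 1e-12)   # quadratic in |g|
  expect_error(bValue(delta = 12e-3, Delta = 11.5e-3, gMag = 1), "delta")
  # algebraic inversion round trip at b = 1000 s/mm^2
  g <- gradientForB(1000, delta = 3.6e-3, Delta = 11.5e-3)
  expect_equal(bValue(delta = 3.6e-3, Delta = 11.5e-3, gMag = g), 1000,
               tolerance = 1e-9)
  expect_gt(g, 0)
})

test_that("free-water RMS displacement behaves as sqrt(2 D Delta)", {
  expect_equal(rmsDisplacement(2.3e-3, 0), 0)
  d1 <- rmsDisplacement(2.3e-3, 11.5e-3)
  expect_equal(round(d1), 7)                    # ~7 um for free water
  expect_equal(rmsDisplacement(2.3e-3, 4 * 11.5e-3) / d1, 2,
               tolerance = 1e-12)               # quadrupling Delta doubles it
  expect_error(rmsDisplacement(-1, 1), "diffusivity")
})

test_that("noiseless tensor fit is exact for 6- and 12-direction schemes", {
  ph <- makeSlabPhantom(phantomSpec(shape = c(4L, 4L, 4L)),
                        normal = c(2, 1, 2) / 3)
  tf <- makeTensorField(ph$truth, c(1.7, 1.0, 0.7) * 1e-3)
  for (nd in c(6L, 12L)) {
    sch <- defaultGradientScheme(nd, bValue = 1000)
    dwi <- simulateDWI(tf, sch, S0 = 100)
    fit <- fitTensor(dwi, sch)
    relErr <- max(abs(tensorComponents(fit@tensors) - tensorComponents(tf))) /
      max(abs(tensorComponents(tf)))
    expect_lt(relErr, 1e-9)
    # eigen-assignment: e1 is the myocyte axis on anisotropic data
    dev <- axialAngle(flatField(putativeMyocyte(fit@eigen)),
                      flatField(ph$truth@m))
    expect_lt(max(dev), 2)
    expect_false(any(fit@flags$missing))
    expect_false(any(fit@flags$clampedNegative))
  }
})

test_that("isotropic signals give FA 0 and set the arbitrary-eigenvector flag", {
  ph <- makeSlabPhantom(phantomSpec(shape = c(3L, 3L, 3L)), c(0, 0, 1))
  iso <- makeTensorField(ph$truth, c(1, 1, 1) * 1e-3)
  sch <- defaultGradientScheme(6)
  fit <- fitTensor(simulateDWI(iso, sch, S0 = 50), sch)
  expect_lt(max(fit@fa), 1e-6)
  expect_true(all(fit@flags$isotropic))
})

test_that("non-positive signals are flagged missing, not fitted", {
  ph <- makeSlabPhantom(phantomSpec(shape = c(3L, 3L, 3L)), c(0, 0, 1))
  tf <- makeTensorField(ph$truth)
  sch <- defaultGradientScheme(6)
  dwi <- simulateDWI(tf, sch, S0 = 100)
  dwi[1, 1, 1, 3] <- 0
  fit <- fitTensor(dwi, sch)
  expect_true(fit@flags$missing[1, 1, 1])
  expect_equal(sum(fit@flags$missing), 1L)
  expect_true(is.na(fit@fa[1, 1, 1]))
})

test_that("collinear directions are rejected as a configuration error", {
  g <- matrix(rep(c(1, 0, 0), 6), ncol = 3, byrow = TRUE)
  sch <- gradientScheme(directions = rbind(c(0, 0, 0), g),
                        bvalues = c(0, rep(1000, 6)))
  dwi <- array(1, c(2, 2, 2, 7))
  expect_error(fitTensor(dwi, sch), "collinear")
})

test_that("fractional anisotropy has the right limits and formula", {
  expect_equal(fractionalAnisotropy(c(1, 1, 1) * 1e-3), 0)
  expect_equal(fractionalAnisotropy(c(1, 0, 0)), 1)
  ev <- c(2, 1, 0.5) * 1e-3
  # independent direct evaluation of the standard formula
  mb <- mean(ev)
  expected <- sqrt(3 / 2) * sqrt(sum((ev - mb)^2)) / sqrt(sum(ev^2))
  expect_equal(fractionalAnisotropy(ev), expected, tolerance = 1e-12)
  expect_true(is.na(fractionalAnisotropy(c(0, 0, 0))))
  # rotation invariance: same eigenvalues, rotated tensor field
  ph1 <- makeSlabPhantom(phantomSpec(shape = c(3L, 3L, 3L)), c(0, 0, 1))
  ph2 <- makeSlabPhantom(phantomSpec(shape = c(3L, 3L, 3L)), c(1, 2, 2) / 3)
  f1 <- fitTensor(simulateDWI(makeTensorField(ph1$truth),
                              defaultGradientScheme(12)),
                  defaultGradientScheme(12))
  f2 <- fitTensor(simulateDWI(makeTensorField(ph2$truth),
                              defaultGradientScheme(12)),
                  defaultGradientScheme(12))
  expect_equal(f1@fa, f2@fa, tolerance = 1e-9)
})

test_that("noisy 12-direction fits match a nonlinear-fit Monte-Carlo oracle", {
  set.seed(42)
  nvox <- 200L
  sch <- defaultGradientScheme(12L, bValue = 1000)
  truthTriad <- qr.Q(qr(matrix(rnorm(9), 3)))
  ev <- c(1.7, 1.0, 0.7) * 1e-3
  D <- truthTriad %*% diag(ev) %*% t(truthTriad)
  comp <- array(0, c(nvox, 1, 1, 6))
  comp[, 1, 1, ] <- matrix(rep(c(D[1, 1], D[2, 2], D[3, 3],
                                 D[1, 2], D[1, 3], D[2, 3]), each = nvox),
                           nvox)
  tf <- TensorField(comp, 1)
  S0 <- 100
  dwi <- simulateDWI(tf, sch, S0 = S0, noiseSigma = 0.02 * S0, seed = 99L)
  fit <- fitTensor(dwi, sch)
  e1 <- flatField(putativeMyocyte(fit@eigen))
  errLin <- axialAngle(e1, matrix(truthTriad[, 1], nvox, 3, byrow = TRUE))

  # oracle: per-voxel nonlinear least squares on the signal model
  g <- sch@directions[sch@bvalues > 0, ]
  b <- sch@bvalues[sch@bvalues > 0]
  X <- b * cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2, 2 * g[, 1] * g[, 2],
                 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3])
  errNl <- numeric(nvox)
  for (i in seq_len(nvox)) {
    S <- dwi[i, 1, 1, ]
    s0i <- S[1]; Sd <- S[-1]
    md <- mean(-log(Sd / s0i) / b)
    par0 <- c(s0i, md, md, md, 0, 0, 0)
    obj <- function(p) sum((Sd - p[1] * exp(-drop(X %*% p[2:7])))^2)
    p <- optim(par0, obj, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14,
                              parscale = c(s0i, rep(1e-3, 6))))$par
    Dm <- matrix(c(p[2], p[5], p[6], p[5], p[3], p[7], p[6], p[7], p[4]), 3)
    v1 <- eigen(Dm, symmetric = TRUE)$vectors[, 1]
    errNl[i] <- axialAngle(v1, truthTriad[, 1])
  }
  expect_lt(mean(errLin), 5)
  expect_lt(mean(errNl), 5)
  expect_lt(abs(mean(errLin) - mean(errNl)), 1)
})
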