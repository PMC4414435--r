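# Independent oracles used across the suite. These deliberately avoid the
# package's implementation paths: plain loops, explicit sorting, explicit
# truth tables, and textbook estimators.

# --- direct (spatial-domain) correlation along one axis, mirror padding ----
mirrorIndex <- function(i, n) {
  # reflect about the boundary samples without duplicating the edge
  while (i < 1L || i > n) {
    if (i < 1L) i <- 2L - i
    if (i > n) i <- 2L * n - i
  }
  i
}

directApplyTemplate <- function(vol, template, axis) {
  d <- dim(vol)
  h <- (length(template) - 1L) %/% 2L
  out <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    acc <- 0
    for (m in -h:h) {
      idx <- c(i, j, k)
      idx[axis] <- mirrorIndex(idx[axis] + m, d[axis])
      acc <- acc + template[m + h + 1L] * vol[idx[1], idx[2], idx[3]]
    }
    out[i, j, k] <- acc
  }
  out
}

# --- sorting-based summary statistics oracle ------------------------------
sortingQuantile <- function(xs, p) {
  # linear interpolation between order statistics (type 7)
  xs <- sort(xs)
  n <- length(xs)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

sortingSummary <- function(xs) {
  xs <- xs[is.finite(xs)]
  med <- sortingQuantile(xs, 0.5)
  list(median = med,
       mad = sortingQuantile(abs(xs - med), 0.5),
       iqr = sortingQuantile(xs, 0.75) - sortingQuantile(xs, 0.25),
       mean = sum(xs) / length(xs),
       sd = sqrt(sum((xs - sum(xs) / length(xs))^2) / (length(xs) - 1)))
}

# --- 3x3 neighbourhood truth tables for the morphology ops ----------------
# p: 3x3 binary matrix; returns the output value of the centre pixel.
ringOrder <- rbind(c(1, 1), c(1, 2), c(1, 3), c(2, 3),
                   c(3, 3), c(3, 2), c(3, 1), c(2, 1))

cleanOracle <- function(p) {
  nb <- sum(p) - p[2, 2]
  if (p[2, 2] == 1 && nb == 0) 0L else p[2, 2]
}

fillOracle <- function(p) {
  nb <- sum(p) - p[2, 2]
  if (p[2, 2] == 0 && nb == 8) 1L else p[2, 2]
}

bridgeOracle <- function(p) {
  if (p[2, 2] == 1) return(1L)
  ring <- apply(ringOrder, 1, function(rc) p[rc[1], rc[2]])
  fgIdx <- which(ring == 1)
  if (length(fgIdx) < 2) return(0L)
  # components of the ring under 8-adjacency, found by explicit BFS over
  # ring positions (adjacent ring positions are 8-adjacent pixels)
  comp <- rep(0L, 8)
  cur <- 0L
  for (st in fgIdx) {
    if (comp[st] > 0) next
    cur <- cur + 1L
    queue <- st
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      if (comp[q] > 0) next
      comp[q] <- cur
      for (nb in c(q %% 8 + 1, (q - 2) %% 8 + 1))
        if (ring[nb] == 1 && comp[nb] == 0) queue <- c(queue, nb)
    }
  }
  if (max(comp) >= 2) 1L else 0L
}

erodeOracle <- function(m) {
  out <- m * 0L
  nr <- nrow(m); nc <- ncol(m)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    all1 <- TRUE
    for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj
      v <- if (ii < 1 || ii > nr || jj < 1 || jj > nc) 0L else m[ii, jj]
      if (v == 0L) all1 <- FALSE
    }
    out[i, j] <- if (all1) 1L else 0L
  }
  out
}

dilateOracle <- function(m) {
  out <- m * 0L
  nr <- nrow(m); nc <- ncol(m)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    any1 <- FALSE
    for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj
      v <- if (ii < 1 || ii > nr || jj < 1 || jj > nc) 0L else m[ii, jj]
      if (v == 1L) any1 <- TRUE
    }
    out[i, j] <- if (any1) 1L else 0L
  }
  out
}

# --- von Mises-Fisher sampling and maximum-likelihood concentration -------
sampleVMF <- function(n, mu, kappa) {
  # Wood (1994) rejection sampler for the 3-sphere
  mu <- mu / sqrt(sum(mu^2))
  b <- (-2 * kappa + sqrt(4 * kappa^2 + 4)) / 2
  x0 <- (1 - b) / (1 + b)
  cc <- kappa * x0 + 2 * log(1 - x0^2)
  out <- matrix(0, n, 3)
  # orthonormal completion of mu
  ref <- if (abs(mu[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v1 <- ref - sum(ref * mu) * mu; v1 <- v1 / sqrt(sum(v1^2))
  v2 <- c(mu[2] * v1[3] - mu[3] * v1[2], mu[3] * v1[1] - mu[1] * v1[3],
          mu[1] * v1[2] - mu[2] * v1[1])
  for (i in seq_len(n)) {
    repeat {
      z <- rbeta(1, 1, 1)
      w <- (1 - (1 + b) * z) / (1 - (1 - b) * z)
      u <- runif(1)
      if (kappa * w + 2 * log(1 - x0 * w) - cc >= log(u)) break
    }
    th <- runif(1, 0, 2 * pi)
    out[i, ] <- w * mu + sqrt(1 - w^2) * (cos(th) * v1 + sin(th) * v2)
  }
  out
}

mlConcentration <- function(normals) {
  # maximum-likelihood kappa: solve coth(k) - 1/k = Rbar for the resultant
  # of the (sign-aligned) sample
  mu <- colSums(normals)
  mu <- mu / sqrt(sum(mu^2))
  Rbar <- sqrt(sum(colSums(normals)^2)) / nrow(normals)
  uniroot(function(k) 1 / tanh(k) - 1 / k - Rbar,
          c(1e-6, 1e4), tol = 1e-10)$root
}

# --- brute-force slab phantom voxel loop ----------------------------------
slabOracle <- function(spec, normal) {
  n <- normal / sqrt(sum(normal^2))
  d <- spec@shape
  out <- array(0, d)
  pw <- log(0.5) / log((1 + cos(pi * spec@intersticeFraction)) / 2)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    pos <- (c(i, j, k) - 1) * spec@spacing
    u <- sum(pos * n) / spec@laminaPeriod
    out[i, j, k] <- spec@baseline +
      spec@contrast * ((1 + cos(2 * pi * u)) / 2)^pw
  }
  out
}

# --- misc -----------------------------------------------------------------
rotationMatrix <- function(axis, angleDeg) {
  a <- angleDeg * pi / 180
  u <- axis / sqrt(sum(axis^2))
  K <- rbind(c(0, -u[3], u[2]), c(u[3], 0, -u[1]), c(-u[2], u[1], 0))
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

flatField <- function(a) matrix(a, prod(dim(a)[1:3]), dim(a)[4])

constantField <- function(dims, v) {
  matrix(v, prod(dims), 3, byrow = TRUE)
}
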