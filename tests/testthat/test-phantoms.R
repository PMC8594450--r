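test_that("blob function matches its closed form", {
  p <- clbParams(amplitude = 2)
  # single blob forced at the field centre, theta = 0
  r <- single_blob_realization(64, 64)
  img <- pixels(sampleCLB(p, realization = r)$image)
  # bulk rendering is single precision; closed-form agreement to ~1e-6
  expect_equal(img[65, 65], 2, tolerance = 1e-6)                 # centre
  expect_equal(img[65, 66], 2 * exp(-2.1 * 1 / 5), tolerance = 1e-6)
  expect_equal(img[66, 65], 2 * exp(-2.1 * 1 / 2), tolerance = 1e-6)
  # direct closed-form evaluation, rotated blob: at offset (1, 0) with a
  # 90-degree rotation the minor axis applies
  expect_equal(iqtask:::.clb_blob_value(1, 0, pi / 2, 2.1, 0.5, 5, 2),
               exp(-2.1 / 2), tolerance = 1e-9)
})

test_that("hybrid far-field rendering tracks exact evaluation", {
  p <- clbParams(fieldSize = 64L, meanClusters = 40)
  r <- sampleCLB(p, seed = 7)
  ex <- sampleCLB(p, realization = r$realization, exact = TRUE)
  a <- pixels(r$image)
  b <- pixels(ex$image)
  expect_gt(min(b), 0)
  expect_lt(sqrt(mean((a - b)^2)) / stats::sd(b), 0.03)
})

test_that("empty cluster realization yields an all-zero background", {
  r <- new("ClusterRealization", nClusters = 0L,
           clusterCenters = matrix(0, 0, 2), blobsPerCluster = integer(0),
           blobOffsets = matrix(0, 0, 2), blobAngles = numeric(0))
  img <- pixels(sampleCLB(clbParams(), realization = r)$image)
  expect_true(all(img == 0))
})

test_that("invalid CLB parameters are rejected", {
  expect_error(clbParams(fieldSize = 0), "positive")
  expect_error(clbParams(amplitude = -1), "positive")
  expect_error(clbParams(meanClusters = -5), "positive")
})

test_that("cluster and blob counts follow their Poisson laws", {
  # tiny field: sampling-statistics test, rendering cost irrelevant
  p <- clbParams(fieldSize = 8L)
  K <- integer(500)
  Nk <- integer(0)
  set.seed(11)
  for (i in 1:500) {
    r <- sampleCLB(p)$realization
    K[i] <- r@nClusters
    if (i <= 50) Nk <- c(Nk, r@blobsPerCluster)
  }
  # mean within 3 standard errors
  expect_lt(abs(mean(K) - 150), 3 * sqrt(150 / 500))
  expect_lt(abs(mean(Nk) - 20), 3 * sqrt(20 / length(Nk)))
  # index of dispersion near 1 for both counts
  expect_gt(var(K) / mean(K), 0.8)
  expect_lt(var(K) / mean(K), 1.25)
  expect_gt(var(Nk) / mean(Nk), 0.8)
  expect_lt(var(Nk) / mean(Nk), 1.25)
})

test_that("CLB intensity is nonnegative and stationary across the field", {
  set.seed(13)
  p <- clb64(amplitude = 1)
  lhalf <- rhalf <- numeric(40)
  for (i in 1:40) {
    img <- pixels(sampleCLB(p)$image)
    expect_gte(min(img), 0)
    lhalf[i] <- mean(img[, 1:32])
    rhalf[i] <- mean(img[, 33:64])
  }
  d <- lhalf - rhalf
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(length(d)) + 1e-12)
})

test_that("rayleigh H0 signal has two maxima separated by L - 2", {
  s <- makeRayleighSignal(rayleighSignalSpec(8L), "H0", 128L)
  px <- pixels(s)
  row <- px[65, ]  # central row
  locmax <- which(diff(sign(diff(row))) == -2) + 1
  locmax <- locmax[row[locmax] > max(row) / 2]
  expect_length(locmax, 2)
  expect_equal(diff(locmax), 6)
})

test_that("rayleigh signals are mirror-symmetric about their centre axis", {
  for (L in 5:9) {
    for (hyp in c("H0", "H1")) {
      px <- pixels(makeRayleighSignal(rayleighSignalSpec(L), hyp, 64L))
      cols <- which(colSums(px) > 1e-9 * max(px))
      ctr2 <- min(cols) + max(cols)       # 2 * centre column
      reflect <- px[, ctr2 - cols]
      expect_equal(px[, cols], reflect, tolerance = 1e-12)
      # vertical symmetry about the central row too
      rows <- which(rowSums(px) > 1e-9 * max(px))
      expect_equal(px[rows, ], px[rev(rows), ], tolerance = 1e-12)
    }
  }
})

test_that("rayleigh H1 equals brute-force convolution of the line", {
  L <- 5L
  n <- 64L
  amp <- 1
  px <- pixels(makeRayleighSignal(
    rayleighSignalSpec(L, amplitude = amp), "H1", n))
  # oracle: dense convolution with the sampled, normalized Gaussian
  sigma <- 1.375
  rad <- ceiling(4 * sigma)
  k1 <- exp(-0.5 * ((-rad):rad)^2 / sigma^2)
  k1 <- k1 / sum(k1)
  k2 <- outer(k1, k1)
  base <- matrix(0, n, n)
  c0 <- (n + 1) / 2
  x1 <- floor(c0 - (L - 1) / 2 + 0.5)
  base[floor(c0 + 0.5), x1:(x1 + L - 1)] <- amp
  oracle <- matrix(0, n, n)
  for (y in 1:n) {
    for (x in 1:n) {
      if (base[y, x] > 0) {
        ys <- max(1, y - rad):min(n, y + rad)
        xs <- max(1, x - rad):min(n, x + rad)
        oracle[ys, xs] <- oracle[ys, xs] +
          base[y, x] * k2[ys - y + rad + 1, xs - x + rad + 1]
      }
    }
  }
  expect_equal(px, oracle, tolerance = 1e-12)
})

test_that("rayleigh signal intensity sums are preserved by the blur", {
  for (L in c(5L, 8L)) {
    a <- 10
    h0 <- pixels(makeRayleighSignal(rayleighSignalSpec(L, amplitude = a),
                                    "H0", 64L))
    h1 <- pixels(makeRayleighSignal(rayleighSignalSpec(L, amplitude = a),
                                    "H1", 64L))
    expect_equal(sum(h0), 2 * a, tolerance = 1e-9)
    expect_equal(sum(h1), L * a, tolerance = 1e-9)
  }
})

test_that("synthetic MC maps are sparse, bounded and clustered", {
  spec <- mcClusterSpec()
  set.seed(17)
  frac <- numeric(100)
  for (i in 1:100) {
    px <- pixels(synthMCCluster(spec))
    frac[i] <- mean(px > 0)
    expect_gte(min(px), 0)
    expect_lte(max(px), 1)
  }
  expect_lt(max(frac), 0.05)
  expect_gt(mean(frac), 0)  # non-degenerate
})

test_that("degenerate MC spec yields exactly one lit pixel", {
  spec <- mcClusterSpec(nMCsRange = c(1L, 1L), mcSizeRange = c(1, 1))
  set.seed(19)
  for (i in 1:20) {
    px <- pixels(synthMCCluster(spec))
    expect_equal(sum(px > 0), 1)
  }
})

test_that("MC spec validation rejects impossible geometry", {
  expect_error(mcClusterSpec(clusterRadius = 150), "canvas")
  expect_error(mcClusterSpec(contrastRange = c(0, 0.5)), "contrast")
  expect_error(mcClusterSpec(nMCsRange = c(0L, 3L)), "lower bound")
})

test_that("rotation and crop behave as a rigid transform", {
  set.seed(23)
  m <- pixels(synthMCCluster(mcClusterSpec()))
  r0 <- pixels(rotateCropCluster(m, 0))
  expect_identical(r0, centralCrop(m, 128L))
  expect_equal(pixels(rotateCropCluster(m, 360)), r0, tolerance = 1e-9)
  # quarter turn equals the exact array quarter-turn
  r90 <- pixels(rotateCropCluster(m, 90))
  expect_equal(r90, t(r0[128:1, ]), tolerance = 1e-6)
  expect_error(rotateCropCluster(m[1:100, 1:100], 10, 128L), "exceeds")
})

test_that("multiplicative MC insertion follows f1 = fb (c s + 1)", {
  fb <- matrix(2, 16, 16)
  s <- matrix(0, 16, 16)
  s[5, 7] <- 1
  out <- insertMC(fb, s, 0.05)
  expect_equal(hypothesis(out), "H1")
  expect_equal(pixels(out)[5, 7], 2.1)
  expect_equal(sum(pixels(out) != 2), 1)
  # c = 0 is the identity
  expect_equal(pixels(insertMC(fb, s, 0)), fb)
  expect_error(insertMC(fb, s, -0.1), ">= 0")
  # monotone in c wherever s > 0 and fb > 0
  set.seed(29)
  fbr <- matrix(runif(256, 0.5, 2), 16, 16)
  sr <- matrix(rbinom(256, 1, 0.2) * runif(256), 16, 16)
  lo <- pixels(insertMC(fbr, sr, 0.02))
  hi <- pixels(insertMC(fbr, sr, 0.07))
  idx <- sr > 0 & fbr > 0
  expect_true(all(hi[idx] > lo[idx]))
  expect_true(all(hi[!idx] == lo[!idx]))
})
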