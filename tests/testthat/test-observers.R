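test_that("covariance fitting recovers degenerate and known statistics", {
  # two identical images per class: zero covariances, exact mean difference
  a <- matrix(1:16, 4, 4)
  b <- a + 2
  arr0 <- array(rep(a, 2), dim = c(4, 4, 2))
  arr1 <- array(rep(b, 2), dim = c(4, 4, 2))
  m <- fitCovarianceModel(arr0, arr1)
  expect_true(all(m@covH0 == 0))
  expect_true(all(m@covH1 == 0))
  expect_equal(deltaMean(m), rep(2, 16))
  expect_error(fitCovarianceModel(arr0[, , 1, drop = FALSE], arr1),
               "at least 2")

  # parameter recovery from synthetic Gaussian draws with a known 4x4
  # covariance (images are 2x2)
  K <- matrix(c(2, 0.8, 0.3, 0, 0.8, 1.5, 0.2, 0.1,
                0.3, 0.2, 1.2, 0.4, 0, 0.1, 0.4, 1), 4, 4)
  set.seed(41)
  X0 <- rmvn(1e5, rep(0, 4), K)
  X1 <- rmvn(1e5, rep(1, 4), K)
  mod <- fitCovarianceModel(ens_from_rows(X0, rep("H0", 1e5))@images,
                            ens_from_rows(X1, rep("H1", 1e5))@images)
  expect_lt(max(abs(mod@pooledCov - K)) / max(abs(K)), 0.02)
  expect_lt(max(abs(deltaMean(mod) - 1)), 0.02)
})

test_that("central crop convention gives the centered block", {
  m <- matrix(seq_len(128^2), 128, 128)
  cr <- centralCrop(m, 64L)
  expect_identical(dim(cr), c(64L, 64L))
  expect_identical(cr[1, 1], m[33, 33])  # starts at (N - 64)/2, 0-based
  arr <- array(rnorm(128 * 128 * 3), dim = c(128, 128, 3))
  mod <- fitCovarianceModel(arr, arr + 1, crop = 64L)
  expect_equal(length(mod@meanH0), 4096)
})

test_that("truncated pseudoinverse honors the singular-value threshold", {
  id <- diag(4)
  mod <- new("CovarianceModel", meanH0 = rep(0, 4), meanH1 = rep(1, 4),
             covH0 = id, covH1 = id, pooledCov = id,
             nPerClass = c(10L, 10L))
  expect_equal(truncatedPinv(mod, 1), id)
  expect_equal(truncatedPinv(mod, 1e-6), id)

  D <- diag(c(4, 1))
  mod2 <- new("CovarianceModel", meanH0 = rep(0, 2), meanH1 = rep(1, 2),
              covH0 = D, covH1 = D, pooledCov = D, nPerClass = c(5L, 5L))
  expect_equal(truncatedPinv(mod2, 0.5), diag(c(0.25, 0)))
  expect_error(truncatedPinv(mod2, 1.5), "\\[0, 1\\]")
  expect_error(truncatedPinv(mod2, -0.1), "\\[0, 1\\]")

  # unregularized limit on a well-conditioned covariance
  set.seed(43)
  A <- matrix(rnorm(36), 6, 6)
  K <- crossprod(A) + diag(6)
  mod3 <- new("CovarianceModel", meanH0 = rep(0, 6), meanH1 = rep(1, 6),
              covH0 = K, covH1 = K, pooledCov = K, nPerClass = c(5L, 5L))
  expect_equal(truncatedPinv(mod3, 0) %*% K, diag(6), tolerance = 1e-8)
})

test_that("retained mode count is non-increasing in lambda", {
  set.seed(44)
  A <- matrix(rnorm(64), 8, 8)
  K <- crossprod(A)
  mod <- new("CovarianceModel", meanH0 = rep(0, 8), meanH1 = rep(1, 8),
             covH0 = K, covH1 = K, pooledCov = K, nPerClass = c(5L, 5L))
  grid <- c(0, 10^seq(-6, 0, by = 1))
  modes <- vapply(grid, function(l) rhoTemplate(mod, l)@retainedModes,
                  integer(1))
  expect_true(all(diff(modes) <= 0))
})

test_that("RHO template reduces to the Hotelling template", {
  set.seed(47)
  A <- matrix(rnorm(64), 8, 8)
  K <- crossprod(A) + 0.5 * diag(8)
  delta <- rnorm(8)
  mod <- new("CovarianceModel", meanH0 = rep(0, 8), meanH1 = delta,
             covH0 = K, covH1 = K, pooledCov = K, nPerClass = c(5L, 5L))
  w_rho <- templateWeights(rhoTemplate(mod, 0))
  w_ho <- templateWeights(hoTemplate(mod))
  expect_equal(w_rho, w_ho, tolerance = 1e-8)
  expect_equal(w_ho, as.numeric(solve(K, delta)), tolerance = 1e-10)

  # hand-computed 2-D case: K = diag(1, 4), delta = (1, 1)
  D <- diag(c(1, 4))
  mod2 <- new("CovarianceModel", meanH0 = c(0, 0), meanH1 = c(1, 1),
              covH0 = D, covH1 = D, pooledCov = D, nPerClass = c(5L, 5L))
  expect_equal(templateWeights(rhoTemplate(mod2, 0)), c(1, 0.25))

  # zero mean difference gives a zero template
  mod3 <- new("CovarianceModel", meanH0 = c(1, 2), meanH1 = c(1, 2),
              covH0 = D, covH1 = D, pooledCov = D, nPerClass = c(5L, 5L))
  expect_equal(templateWeights(rhoTemplate(mod3, 0)), c(0, 0))
})

test_that("gabor channel bank matches its closed form", {
  spec <- gaborChannelSpec(gridSize = 33L)
  Tm <- buildGaborMatrix(spec)
  expect_equal(nrow(channelMatrix(Tm)), 60)
  # origin pixel (grid centre) for the two phases of the first passband
  ctr <- 17 + (17 - 1) * 33  # vectorized index of (row 17, col 17)
  expect_equal(channelMatrix(Tm)[1, ctr], 1)            # phase 0
  expect_equal(channelMatrix(Tm)[2, ctr], 0)            # phase pi/2
  # envelope decays to 1/16 at radius w along the zero-phase crest
  w <- 8
  nu <- 6 * log(2) / (pi * w)
  sp2 <- gaborChannelSpec(gridSize = 33L, centerFrequencies = nu,
                          orientations = 0, phases = 0)
  expect_equal(sp2@widths, w, tolerance = 1e-12)
  M2 <- channelMatrix(buildGaborMatrix(sp2))
  idx <- (17 + w) + (17 - 1) * 33  # (row 17 + w, col 17): on the crest
  expect_equal(M2[1, idx], 1 / 16, tolerance = 1e-12)
  # aliasing frequencies are rejected
  expect_error(gaborChannelSpec(centerFrequencies = 0.6), "Nyquist")
})

test_that("CHO equals HO under identity channels and its closed form", {
  set.seed(53)
  K <- matrix(c(1.5, 0.4, 0.1, 0.4, 1.2, 0.2, 0.1, 0.2, 0.9), 3, 3)
  K <- crossprod(chol(K))  # ensure PD
  d <- 3  # use 9-pixel images via a 3x3 grid; q = n with identity channels
  X0 <- rmvn(4000, rep(0, 9), diag(9) + 0.3)
  X1 <- rmvn(4000, rep(c(1, 0, 0), 3), diag(9) + 0.3)
  e0 <- ens_from_rows(X0, rep("H0", 4000))
  e1 <- ens_from_rows(X1, rep("H1", 4000))
  idspec <- gaborChannelSpec(gridSize = 3L, centerFrequencies = 0.1,
                             orientations = 0, phases = 0)
  idchan <- new("ChannelMatrix", mat = diag(9), spec = idspec)
  w_cho <- templateWeights(choTemplate(idchan, e0@images, e1@images))
  mod <- fitCovarianceModel(e0@images, e1@images)
  w_ho <- templateWeights(hoTemplate(mod))
  expect_equal(w_cho, w_ho, tolerance = 1e-6)

  # closed form in channel space for a non-trivial channel matrix
  Tm <- matrix(rnorm(2 * 9), 2, 9)
  chan <- new("ChannelMatrix", mat = Tm, spec = idspec)
  w2 <- templateWeights(choTemplate(chan, e0@images, e1@images))
  V0 <- X0 %*% t(Tm)
  V1 <- X1 %*% t(Tm)
  Kv <- (stats::cov(V0) + stats::cov(V1)) / 2
  expect_equal(w2, as.numeric(solve(Kv, colMeans(V1) - colMeans(V0))),
               tolerance = 1e-10)

  # singular channel covariance raises an informative error
  tiny0 <- ens_from_rows(X0[1:2, ], rep("H0", 2))
  tiny1 <- ens_from_rows(X1[1:2, ], rep("H1", 2))
  bigT <- new("ChannelMatrix", mat = rbind(diag(9), diag(9)), spec = idspec)
  expect_error(choTemplate(bigT, tiny0@images, tiny1@images), "singular")
})

test_that("linear scoring is an order-preserving dot product", {
  w <- new("LinearTemplate", weights = c(1, 2, 3, 4), kind = "HO")
  img <- matrix(c(3, 4, 5, 6), 2, 2)  # column-major vec: 3 4 5 6
  ens <- new("ImagingEnsemble",
             images = array(c(img, 2 * img), dim = c(2, 2, 2)),
             labels = factor(c("H0", "H1"), levels = c("H0", "H1")),
             resolutionClass = "HR")
  ss <- applyLinear(w, ens)
  expect_equal(scoresH0(ss), sum(c(1, 2, 3, 4) * c(3, 4, 5, 6)))
  expect_equal(scoresH1(ss), 2 * scoresH0(ss))
  # zero template scores everything zero
  z <- new("LinearTemplate", weights = rep(0, 4), kind = "HO")
  expect_true(all(c(scoresH0(applyLinear(z, ens)),
                    scoresH1(applyLinear(z, ens))) == 0))
  # permutation equivariance: scores follow the images
  set.seed(59)
  arr <- array(rnorm(2 * 2 * 6), dim = c(2, 2, 6))
  labs <- factor(rep(c("H0", "H1"), 3), levels = c("H0", "H1"))
  e1 <- new("ImagingEnsemble", images = arr, labels = labs,
            resolutionClass = "HR")
  p <- c(5, 3, 1, 6, 4, 2)
  e2 <- e1[p]
  s1 <- applyLinear(w, e1)
  s2 <- applyLinear(w, e2)
  expect_equal(sort(c(scoresH0(s1), scoresH1(s1))),
               sort(c(scoresH0(s2), scoresH1(s2))))
})

test_that("lambda selection maximizes validation AUC with large-lambda ties", {
  set.seed(61)
  K <- diag(8)
  X0 <- rmvn(800, rep(0, 8), K)
  X1 <- rmvn(800, rep(0.4, 8), K)
  # 8 pixels cannot form a square image; use a 2x2x2... use 4-pixel images
  X0 <- X0[, 1:4]; X1 <- X1[, 1:4]
  mod <- fitCovarianceModel(ens_from_rows(X0, rep("H0", 800))@images,
                            ens_from_rows(X1, rep("H1", 800))@images)
  v0 <- ens_from_rows(rmvn(400, rep(0, 4), diag(4)), rep("H0", 400))
  v1 <- ens_from_rows(rmvn(400, rep(0.4, 4), diag(4)), rep("H1", 400))
  sel <- selectLambda(mod, v0@images, v1@images)
  expect_equal(nrow(sel$table), 6)  # default decade grid 1e-9 .. 1e-4
  # well-conditioned: AUC flat across the grid, tie broken to largest
  expect_true(all(abs(sel$table$auc - sel$auc) < 1e-12))
  expect_equal(sel$lambda, 1e-4)
  sel1 <- selectLambda(mod, v0@images, v1@images, grid = 0.5)
  expect_equal(sel1$lambda, 0.5)
  expect_error(selectLambda(mod, v0@images, v1@images, grid = numeric(0)),
               "non-empty")
})

test_that("HO empirical AUC matches the equal-covariance closed form", {
  # 8-dimensional synthetic task with known statistics
  set.seed(67)
  A <- matrix(rnorm(64), 8, 8)
  K <- crossprod(A) + 2 * diag(8)
  delta <- rnorm(8, 0, 0.5)
  snr2 <- as.numeric(t(delta) %*% solve(K, delta))
  target <- pnorm(sqrt(snr2 / 2))
  w <- solve(K, delta)
  n <- 20000
  s0 <- rmvn(n, rep(0, 8), K) %*% w
  s1 <- rmvn(n, delta, K) %*% w
  a <- empiricalAUC(new("ScoreSet", scoresH0 = as.numeric(s0),
                        scoresH1 = as.numeric(s1)))
  expect_lt(abs(a - target), 0.01)
})

test_that("templates and scores are bit-reproducible", {
  ens <- fix_rayleigh_small()
  tr <- ens$hr[1:80]
  sp <- iqtask:::.class_split(tr)
  m1 <- fitCovarianceModel(sp$h0, sp$h1, crop = 16L)
  m2 <- fitCovarianceModel(sp$h0, sp$h1, crop = 16L)
  w1 <- templateWeights(rhoTemplate(ensureSVD(m1), 1e-6))
  w2 <- templateWeights(rhoTemplate(ensureSVD(m2), 1e-6))
  expect_identical(w1, w2)
  t1 <- applyLinear(rhoTemplate(ensureSVD(m1), 1e-6), ens$hr[81:120])
  t2 <- applyLinear(rhoTemplate(ensureSVD(m2), 1e-6), ens$hr[81:120])
  expect_identical(scoresH0(t1), scoresH0(t2))
})
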