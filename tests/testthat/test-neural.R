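test_that("SRCNN architecture has the prescribed shape and size", {
  # parameter count from the architecture arithmetic:
  # 9*9*1*32+32 + 5*5*32*32+32 + 5*5*32*1+1 = 29057
  m <- buildSRCNN(srNetworkSpec(3L), seed = 1)
  expect_equal(countParameters(m), 9 * 9 * 32 + 32 + 25 * 32 * 32 + 32 +
                 25 * 32 + 1)
  expect_equal(countParameters(m), 29057)
  # whole depth grid builds; output shape equals input shape (same padding)
  for (d in 2:8) {
    md <- buildSRCNN(srNetworkSpec(d, hiddenChannels = 4L), seed = d)
    X <- array(rnorm(12 * 12 * 2), dim = c(12, 12, 2))
    out <- iqtask:::.sr_forward(md, X)$out
    expect_identical(dim(out), dim(X))
  }
  expect_error(srNetworkSpec(1L), ">= 2")
})

test_that("network gradients match finite differences", {
  set.seed(2)
  spec <- srNetworkSpec(3L, firstFilter = 3L, hiddenFilter = 3L,
                        hiddenChannels = 4L)
  m <- buildSRCNN(spec, seed = 3)
  X <- array(rnorm(8 * 8 * 2), dim = c(8, 8, 2))
  Tg <- array(rnorm(8 * 8 * 2), dim = c(8, 8, 2))
  res <- iqtask:::.cnn_sr_batch(X, m@params$W, m@params$b, spec$kernels,
                                TRUE, Tg)
  eps <- 1e-6
  for (probe in 1:6) {
    l <- sample(3, 1)
    i <- sample(length(m@params$W[[l]]), 1)
    p1 <- m@params; p1$W[[l]][i] <- p1$W[[l]][i] + eps
    p2 <- m@params; p2$W[[l]][i] <- p2$W[[l]][i] - eps
    fd <- (iqtask:::.cnn_sr_batch(X, p1$W, p1$b, spec$kernels, FALSE,
                                  Tg)$loss -
           iqtask:::.cnn_sr_batch(X, p2$W, p2$b, spec$kernels, FALSE,
                                  Tg)$loss) / (2 * eps)
    expect_lt(abs(res$gW[[l]][i] - fd) / max(abs(fd), 1e-6), 1e-4)
  }

  # residual observer gradients
  om <- buildResnetObserver(observerNetworkSpec(2L, inputSize = 8L,
                                                channels = 4L), seed = 5)
  y <- c(0, 1, 1)
  Xo <- array(rnorm(8 * 8 * 3), dim = c(8, 8, 3))
  r2 <- iqtask:::.cnn_resnet_batch(Xo, om@params, 2L, TRUE, y)
  fd_of <- function(set) {
    (iqtask:::.cnn_resnet_batch(Xo, set(+eps), 2L, FALSE, y)$loss -
     iqtask:::.cnn_resnet_batch(Xo, set(-eps), 2L, FALSE, y)$loss) / (2 * eps)
  }
  checks <- list(
    list(g = r2$grads$stem_W[3],
         set = function(e) { p <- om@params; p$stem_W[3] <- p$stem_W[3] + e; p }),
    list(g = r2$grads$blocks[[1]]$W1[5],
         set = function(e) { p <- om@params; p$blocks[[1]]$W1[5] <- p$blocks[[1]]$W1[5] + e; p }),
    list(g = r2$grads$blocks[[2]]$W2[7],
         set = function(e) { p <- om@params; p$blocks[[2]]$W2[7] <- p$blocks[[2]]$W2[7] + e; p }),
    list(g = r2$grads$head_w[2],
         set = function(e) { p <- om@params; p$head_w[2] <- p$head_w[2] + e; p }),
    list(g = r2$grads$lin_w[10],
         set = function(e) { p <- om@params; p$lin_w[10] <- p$lin_w[10] + e; p })
  )
  for (ch in checks) {
    fd <- fd_of(ch$set)
    expect_lt(abs(ch$g - fd) / max(abs(fd), 1e-6), 1e-3)
  }
})

test_that("SR training converges on the identity task and is deterministic", {
  set.seed(7)
  X <- array(rnorm(16 * 16 * 64), dim = c(16, 16, 64))
  spec <- srNetworkSpec(2L, firstFilter = 5L, hiddenFilter = 3L,
                        hiddenChannels = 8L)
  cfg <- trainingConfig(batchSize = 16L, learningRate = 3e-3,
                        maxEpochs = 25L, seed = 11)
  m <- buildSRCNN(spec, seed = 9)
  tm <- trainSR(m, X, X, cfg = cfg)
  h <- tm@history
  expect_lt(h$trainLoss[nrow(h)], 0.1 * h$trainLoss[1])
  # the selected checkpoint is no worse than the final epoch on validation
  expect_lte(min(h$valLoss), h$valLoss[nrow(h)] + 1e-12)
  # identical rerun
  tm2 <- trainSR(buildSRCNN(spec, seed = 9), X, X, cfg = cfg)
  expect_identical(tm@history, tm2@history)
  expect_identical(tm@params, tm2@params)
})

test_that("applySR preserves labels, size and determinism", {
  ens <- fix_rayleigh_small()
  sub <- ens$lr[1:10]
  spec <- srNetworkSpec(2L, firstFilter = 5L, hiddenFilter = 3L,
                        hiddenChannels = 4L)
  m <- buildSRCNN(spec, seed = 13)
  sr1 <- applySR(m, sub)
  sr2 <- applySR(m, sub)
  expect_identical(images(sr1), images(sr2))
  expect_identical(labels2(sr1), labels2(sub))
  expect_equal(resolutionClass(sr1), "SR")
  expect_identical(dim(images(sr1)), dim(images(sub)))
  # untrained models are flagged in provenance
  expect_match(generationSpec(sr1)$srModel$warning, "untrained")
})

test_that("warm-started observers reproduce the linear template", {
  ens <- fix_rayleigh_small()
  tr <- ens$hr[1:80]
  sp <- iqtask:::.class_split(tr)
  mod <- fitCovarianceModel(sp$h0, sp$h1, crop = 32L)
  rho <- rhoTemplate(ensureSVD(mod), 1e-5)
  obs <- buildResnetObserver(
    observerNetworkSpec(2L, inputSize = 32L, channels = 4L),
    warmStart = rho, seed = 17)
  lin <- applyLinear(rho, ens$hr[81:120])
  net <- scoreObserver(obs, ens$hr[81:120])
  expect_gt(cor(c(scoresH0(lin), scoresH1(lin)),
                c(scoresH0(net), scoresH1(net)),
                method = "spearman"), 0.9)
  # one score per image
  expect_length(c(scoresH0(net), scoresH1(net)), 40)
  expect_error(buildResnetObserver(
    observerNetworkSpec(2L, inputSize = 16L, channels = 4L),
    warmStart = rho), "warm-start")
})

test_that("observer training separates a separable toy task", {
  set.seed(19)
  n <- 40
  X <- array(rnorm(8 * 8 * 2 * n, 0, 0.1), dim = c(8, 8, 2 * n))
  X[, , (n + 1):(2 * n)] <- X[, , (n + 1):(2 * n)] + 1
  labs <- factor(rep(c("H0", "H1"), each = n), levels = c("H0", "H1"))
  perm <- sample(2 * n)
  ens <- new("ImagingEnsemble", images = X[, , perm],
             labels = labs[perm], resolutionClass = "HR")
  obs <- buildResnetObserver(observerNetworkSpec(2L, inputSize = 8L,
                                                 channels = 4L), seed = 23)
  cfg <- trainingConfig(batchSize = 16L, learningRate = 5e-3,
                        maxEpochs = 8L, seed = 23)
  tobs <- trainObserver(obs, ens[1:60], ens[61:80], cfg)
  sc <- scoreObserver(tobs, ens)
  expect_equal(empiricalAUC(sc), 1.0)
  expect_error(trainObserver(obs, ens[which(labels2(ens) == "H0")],
                             ens[61:80], cfg), "both classes")
})

test_that("semionline training redraws noise and flips quadruple the data", {
  ens <- buildTaskEnsembles("rayleigh", 10, list(clb = clb64()), seed = 29,
                            keepNoiseless = TRUE)
  obs <- buildResnetObserver(observerNetworkSpec(1L, inputSize = 16L,
                                                 channels = 2L), seed = 31)
  cfg <- trainingConfig(batchSize = 10L, learningRate = 1e-3,
                        maxEpochs = 2L, seed = 31, semionlineNoise = TRUE)
  # runs, and requires the stored noiseless composites
  t1 <- trainObserver(obs, ens$hr, ens$hr, cfg)
  expect_s4_class(t1, "ConvNetModel")
  bare <- ens$hr
  bare@generationSpec <- list()
  expect_error(trainObserver(obs, bare, ens$hr, cfg), "keepNoiseless")
  # with a fixed seed the redrawn-noise run is reproducible but differs
  # from the offline-noise run
  t2 <- trainObserver(obs, ens$hr, ens$hr, cfg)
  expect_identical(t1@history, t2@history)
  cfg_off <- trainingConfig(batchSize = 10L, learningRate = 1e-3,
                            maxEpochs = 2L, seed = 31)
  t3 <- trainObserver(obs, ens$hr, ens$hr, cfg_off)
  expect_false(identical(t1@history$trainLoss, t3@history$trainLoss))

  aug <- iqtask:::.flip_augment(images(ens$hr), rep(0:1, 10))
  expect_equal(dim(aug$X)[3], 4 * nImages(ens$hr))
  expect_length(aug$y, 4 * nImages(ens$hr))
})
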