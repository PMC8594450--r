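test_that("empirical AUC follows the Mann-Whitney pair count", {
  expect_equal(empiricalAUC(new("ScoreSet", scoresH0 = c(1, 2),
                                scoresH1 = c(1.5, 3))), 0.75)
  expect_equal(empiricalAUC(new("ScoreSet", scoresH0 = 1:5,
                                scoresH1 = 6:10)), 1)
  expect_equal(empiricalAUC(new("ScoreSet", scoresH0 = c(1, 2, 3),
                                scoresH1 = c(1, 2, 3))), 0.5)
  expect_error(empiricalAUC(new("ScoreSet", scoresH0 = numeric(0),
                                scoresH1 = 1)), "non-empty")
  # invariance under strictly monotone transforms; negation symmetry
  set.seed(3)
  s0 <- rnorm(50)
  s1 <- rnorm(50, 0.7)
  a <- empiricalAUC(new("ScoreSet", scoresH0 = s0, scoresH1 = s1))
  expect_equal(empiricalAUC(new("ScoreSet", scoresH0 = exp(s0),
                                scoresH1 = exp(s1))), a)
  expect_equal(empiricalAUC(new("ScoreSet", scoresH0 = -s0,
                                scoresH1 = -s1)), 1 - a)
})

test_that("DeLong interval matches the point estimate and pROC", {
  set.seed(5)
  s0 <- rnorm(100)
  s1 <- rnorm(100, 1)
  ss <- new("ScoreSet", scoresH0 = s0, scoresH1 = s1)
  r <- deLongCI(ss)
  expect_equal(auc(r), empiricalAUC(ss))
  expect_lte(r@ciLow, auc(r))
  expect_gte(r@ciHigh, auc(r))
  skip_if_not_installed("pROC")
  pr <- pROC::roc(response = c(rep(0, 100), rep(1, 100)),
                  predictor = c(s0, s1), quiet = TRUE, direction = "<")
  ci <- suppressWarnings(pROC::ci.auc(pr, method = "delong"))
  expect_equal(auc(r), as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  expect_equal(c(r@ciLow, r@ciHigh), as.numeric(ci[c(1, 3)]),
               tolerance = 1e-9)
})

test_that("DeLong variance agrees with the bootstrap", {
  set.seed(7)
  s0 <- rnorm(100)
  s1 <- rnorm(100, 1)
  ss <- new("ScoreSet", scoresH0 = s0, scoresH1 = s1)
  r <- deLongCI(ss)
  boots <- replicate(2000, {
    empiricalAUC(new("ScoreSet",
                     scoresH0 = sample(s0, replace = TRUE),
                     scoresH1 = sample(s1, replace = TRUE)))
  })
  expect_lt(abs(r@variance - var(boots)) / var(boots), 0.2)
})

test_that("DeLong CI covers the analytic AUC at the nominal rate", {
  target <- pnorm(1 / sqrt(2))
  set.seed(11)
  cover <- logical(500)
  for (i in 1:500) {
    r <- deLongCI(new("ScoreSet", scoresH0 = rnorm(200),
                      scoresH1 = rnorm(200, 1)))
    cover[i] <- r@ciLow <= target && target <= r@ciHigh
  }
  expect_gte(mean(cover), 0.9)
})

test_that("DeLong CI width shrinks like 1/sqrt(n)", {
  set.seed(13)
  s0 <- rnorm(1600)
  s1 <- rnorm(1600, 0.8)
  width <- function(n) {
    r <- deLongCI(new("ScoreSet", scoresH0 = s0[1:n], scoresH1 = s1[1:n]))
    r@ciHigh - r@ciLow
  }
  ratio <- width(100) / width(1600)
  expect_gt(ratio, 2.4)  # ideal 4
  expect_lt(ratio, 6.5)
  # degenerate separation collapses the interval and is flagged
  rdeg <- deLongCI(new("ScoreSet", scoresH0 = 1:10, scoresH1 = 21:30))
  expect_true(rdeg@degenerate)
  expect_equal(c(rdeg@ciLow, rdeg@ciHigh), c(1, 1))
})

test_that("IQ metrics follow their closed forms", {
  set.seed(17)
  a <- array(rnorm(16 * 16 * 3), dim = c(16, 16, 3))
  m <- iqMetrics(a, a, peak = 1)
  expect_equal(m@ensembleMSE, 0)
  expect_equal(m@ssim, 1)
  expect_true(is.infinite(m@psnr))
  # peak 1, MSE 0.01 -> PSNR 20 dB
  b <- a + 0.1
  m2 <- iqMetrics(a, b, peak = 1)
  expect_equal(m2@ensembleMSE, 0.01, tolerance = 1e-12)
  expect_equal(m2@psnr, 20, tolerance = 1e-9)
  # constant ensembles: zero-variance closed form
  ca <- array(2, dim = c(16, 16, 2))
  cb <- array(3, dim = c(16, 16, 2))
  peak <- 5
  C1 <- (0.01 * peak)^2
  m3 <- iqMetrics(ca, cb, peak = peak)
  expect_equal(m3@ssim, (2 * 6 + C1) / (4 + 9 + C1), tolerance = 1e-12)
  expect_error(iqMetrics(ca, cb[, , 1, drop = FALSE]), "shapes differ")
})

test_that("windowed SSIM reproduces the reference implementation", {
  # frozen oracle: scikit-image structural_similarity on this exact
  # fixture (gaussian_weights, sigma 1.5, use_sample_covariance = FALSE,
  # data_range = 10) gives 0.9476287835
  set.seed(42)
  a <- matrix(runif(64 * 64), 64, 64)
  a <- iqtask:::.gauss_filter(a, 2, -1L) * 10
  b <- a + matrix(rnorm(64 * 64, 0, 0.1), 64, 64)
  expect_equal(ssimImage(a, b, peak = 10), 0.9476287835, tolerance = 1e-8)
})

test_that("batched fidelity evaluation matches the one-shot metrics", {
  specs <- list(clb = clb64(1.764), mc = mcClusterSpec(clusterRadius = 15))
  fid <- evaluateTaskFidelity("mc", nPairs = 24, specs = specs, seed = 5,
                              peak = 128.5, batchPairs = 8)
  expect_equal(fid$nPairs, 24)
  expect_true(is.finite(fid$mse) && fid$mse > 0)
  expect_true(fid$ssim > 0.9 && fid$ssim <= 1)
  expect_equal(fid$psnr, 20 * log10(128.5) - 10 * log10(fid$mse))
  # deterministic in the seed
  fid2 <- evaluateTaskFidelity("mc", nPairs = 24, specs = specs, seed = 5,
                               peak = 128.5, batchPairs = 8)
  expect_identical(fid, fid2)
})
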