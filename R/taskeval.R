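## Traditional IQ metrics, ROC/AUC with DeLong confidence intervals and the
## experiment drivers.

#' Structural similarity between two images
#'
#' Standard windowed SSIM: local statistics from an 11x11 Gaussian window
#' (sigma 1.5), stability constants C1 = (0.01 peak)^2 and
#' C2 = (0.03 peak)^2; the mean is taken over the window-valid interior
#' (a 5-pixel border is excluded), which makes the value independent of the
#' padding convention.
#'
#' @param ref,test numeric matrices of identical shape.
#' @param peak dynamic-range reference.
#' @return scalar SSIM.
#' @export
ssimImage <- function(ref, test, peak) {
  if (!all(dim(ref) == dim(test))) stop("image shapes differ")
  .assert_scalar_pos(peak, "peak")
  C1 <- (0.01 * peak)^2
  C2 <- (0.03 * peak)^2
  r <- 5L
  f <- function(m) .gauss_filter(m, 1.5, r)
  mu1 <- f(ref)
  mu2 <- f(test)
  s11 <- f(ref * ref) - mu1^2
  s22 <- f(test * test) - mu2^2
  s12 <- f(ref * test) - mu1 * mu2
  ss <- ((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
    ((mu1^2 + mu2^2 + C1) * (s11 + s22 + C2))
  n <- nrow(ref)
  if (n > 2 * r) {
    ss <- ss[(r + 1):(n - r), (r + 1):(ncol(ref) - r)]
  }
  mean(ss)
}

#' Traditional IQ metrics for an aligned ensemble pair
#'
#' Ensemble MSE is the grand mean of squared pixel differences; PSNR is
#' \eqn{20 \log_{10}(peak) - 10 \log_{10}(MSE)} (reported as +Inf when the
#' MSE is zero); SSIM is the per-image windowed SSIM averaged over the
#' ensemble.
#'
#' @param ref,test aligned \code{\link{ImagingEnsemble}}s or (H, W, N)
#'   arrays.
#' @param peak dynamic-range reference, or "auto" for the maximum pixel
#'   value of \code{ref}.
#' @return an \code{\link{IQMetrics}} object.
#' @export
iqMetrics <- function(ref, test, peak = "auto") {
  a <- if (is(ref, "ImagingEnsemble")) ref@images else ref
  b <- if (is(test, "ImagingEnsemble")) test@images else test
  if (!all(dim(a) == dim(b))) stop("ensemble shapes differ")
  if (identical(peak, "auto")) peak <- max(a)
  .assert_scalar_pos(peak, "peak")
  mse <- mean((a - b)^2)
  psnr <- if (mse == 0) Inf else 20 * log10(peak) - 10 * log10(mse)
  N <- dim(a)[3]
  ss <- vapply(seq_len(N),
               function(i) ssimImage(a[, , i], b[, , i], peak), numeric(1))
  new("IQMetrics", ensembleMSE = mse, psnr = psnr, ssim = mean(ss),
      peak = peak, nImages = as.integer(N))
}

#' Empirical (Mann-Whitney) AUC
#'
#' Mean over all (H0, H1) score pairs of 1 if the H1 score is larger, 0.5
#' if tied, 0 otherwise; computed via midranks.
#'
#' @param scores a \code{\link{ScoreSet}}.
#' @return scalar AUC in [0, 1].
#' @examples
#' s <- new("ScoreSet", scoresH0 = c(1, 2), scoresH1 = c(1.5, 3))
#' empiricalAUC(s)  # 0.75
#' @export
empiricalAUC <- function(scores) {
  s0 <- scores@scoresH0
  s1 <- scores@scoresH1
  if (length(s0) == 0 || length(s1) == 0) {
    stop("both classes must be non-empty")
  }
  r <- rank(c(s0, s1), ties.method = "average")
  n0 <- length(s0)
  n1 <- length(s1)
  (sum(r[(n0 + 1):(n0 + n1)]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

#' DeLong confidence interval for the empirical AUC
#'
#' Nonparametric structural-components variance estimate with a
#' normal-approximation two-sided interval, clipped to [0, 1].  When every
#' pair is ordered (AUC exactly 0 or 1) the variance collapses and the
#' interval degenerates to a point; the result is flagged.
#'
#' @param scores a \code{\link{ScoreSet}}.
#' @param level confidence level (default 0.95).
#' @return an \code{\link{ROCResult}}.
#' @export
deLongCI <- function(scores, level = 0.95) {
  s0 <- scores@scoresH0
  s1 <- scores@scoresH1
  n0 <- length(s0)
  n1 <- length(s1)
  if (n0 < 2 || n1 < 2) stop("need at least 2 scores per class")
  a <- empiricalAUC(scores)
  # placement values (structural components)
  v10 <- vapply(s1, function(t1) {
    (sum(t1 > s0) + 0.5 * sum(t1 == s0)) / n0
  }, numeric(1))
  v01 <- vapply(s0, function(t0) {
    (sum(s1 > t0) + 0.5 * sum(s1 == t0)) / n1
  }, numeric(1))
  va <- var(v10) / n1 + var(v01) / n0
  degen <- !is.finite(va) || va <= 0
  if (degen) va <- 0
  z <- qnorm(1 - (1 - level) / 2)
  lo <- max(0, a - z * sqrt(va))
  hi <- min(1, a + z * sqrt(va))
  new("ROCResult", auc = a, ciLow = lo, ciHigh = hi, variance = va,
      n0 = as.integer(n0), n1 = as.integer(n1), level = level,
      degenerate = degen)
}

#' Evaluate LR-versus-HR fidelity of a task simulation
#'
#' Simulates paired HR/LR ensembles for a task in memory-bounded batches
#' and accumulates the traditional IQ metrics of the LR images relative to
#' HR: ensemble MSE (grand mean over all pixels and pairs), PSNR from the
#' accumulated MSE, and the mean per-image SSIM (computed when a numeric
#' peak is available).
#'
#' @param task "rayleigh" or "mc".
#' @param nPairs total number of HR/LR pairs (split over both classes).
#' @param specs spec list as in \code{\link{buildTaskEnsembles}}; defaults
#'   to the calibrated task configuration via
#'   \code{\link{defaultExperimentConfig}}.
#' @param seed master seed.
#' @param peak PSNR/SSIM reference; "auto" tracks the maximum HR pixel
#'   value (SSIM is then skipped, since it needs the peak up front).
#' @param batchPairs pairs simulated per batch.
#' @param ssim compute the per-image SSIM (requires numeric \code{peak}).
#' @return list with \code{mse}, \code{psnr}, \code{ssim}, \code{peak},
#'   \code{nPairs}.
#' @export
evaluateTaskFidelity <- function(task = c("rayleigh", "mc"), nPairs = 1000L,
                                 specs = NULL, seed = 1L, peak = NULL,
                                 batchPairs = 250L, ssim = NULL) {
  task <- match.arg(task)
  if (is.null(specs)) {
    cfgd <- defaultExperimentConfig(task)
    specs <- configSpecs(cfgd)
    if (task == "rayleigh") {
      specs$signal <- rayleighSignalSpec(cfgd$signal$signal_length,
                                         cfgd$signal$blur_sigma,
                                         cfgd$signal$amplitude)
    }
    if (is.null(peak)) peak <- cfgd$peak
  }
  if (is.null(peak)) peak <- "auto"
  if (is.null(ssim)) ssim <- is.numeric(peak)
  if (ssim && !is.numeric(peak)) {
    stop("SSIM accumulation needs a numeric peak")
  }
  sum_sq <- 0
  n_px <- 0
  sum_ssim <- 0
  n_img <- 0
  peak_seen <- -Inf
  done <- 0L
  b <- 0L
  while (done < nPairs) {
    nb <- min(batchPairs, nPairs - done)
    # class-balanced batches (alternate remainder across batches)
    n_per <- ceiling(nb / 2)
    ens <- buildTaskEnsembles(task, n_per, specs,
                              seed = seedStream(seed, "misc", offset = b))
    keep <- seq_len(nb)
    a <- ens$hr@images[, , keep, drop = FALSE]
    l <- ens$lr@images[, , keep, drop = FALSE]
    sum_sq <- sum_sq + sum((a - l)^2)
    n_px <- n_px + length(a)
    peak_seen <- max(peak_seen, max(a))
    if (ssim) {
      for (i in seq_len(nb)) {
        sum_ssim <- sum_ssim + ssimImage(a[, , i], l[, , i], peak)
      }
      n_img <- n_img + nb
    }
    done <- done + nb
    b <- b + 1L
  }
  mse <- sum_sq / n_px
  pk <- if (is.numeric(peak)) peak else peak_seen
  list(mse = mse,
       psnr = if (mse == 0) Inf else 20 * log10(pk) - 10 * log10(mse),
       ssim = if (ssim) sum_ssim / n_img else NA_real_,
       peak = pk, nPairs = done)
}

## split an ensemble into its class sub-arrays
.class_split <- function(ens) {
  list(h0 = ens@images[, , ens@labels == "H0", drop = FALSE],
       h1 = ens@images[, , ens@labels == "H1", drop = FALSE])
}

## fit RHO (with validation lambda selection) and Gabor CHO on train/val
## ensembles and score the test ensemble; returns named ROCResult list
.linear_observer_aucs <- function(train, val, test, crop, lambdaGrid,
                                  choRidge = 0) {
  tr <- .class_split(train)
  va <- .class_split(val)
  model <- fitCovarianceModel(tr$h0, tr$h1, crop = crop)
  model <- ensureSVD(model)
  sel <- selectLambda(model, va$h0, va$h1, grid = lambdaGrid)
  rho <- rhoTemplate(model, sel$lambda)
  cho <- choTemplate(buildGaborMatrix(gaborChannelSpec(gridSize = crop)),
                     tr$h0, tr$h1, crop = crop, ridge = choRidge)
  list(
    RHO = deLongCI(applyLinear(rho, test)),
    CHO = deLongCI(applyLinear(cho, test)),
    lambda = sel$lambda
  )
}

.iq_row <- function(iq) {
  data.frame(mse = iq@ensembleMSE, psnr = iq@psnr, ssim = iq@ssim)
}

.roc_row <- function(roc) {
  data.frame(auc = roc@auc, ciLow = roc@ciLow, ciHigh = roc@ciHigh)
}

#' Signal-length sweep for the Rayleigh task
#'
#' For each signal length L, builds training/validation/test HR and LR
#' ensembles (plus SR when an SR model is supplied or configured), fits the
#' RHO (with validation-selected lambda) and Gabor CHO per resolution
#' class, and reports AUC with DeLong CIs and traditional IQ metrics.
#'
#' @param config list with components \code{lengths} (default 5:9),
#'   \code{clb}, \code{signalAmplitude}, \code{nTrainPerClass},
#'   \code{nValPerClass}, \code{nTestPerClass}, \code{crop},
#'   \code{lambdaGrid}, \code{seed}, and optionally \code{srModel} (a
#'   trained SRCNN applied to the LR ensembles).
#' @return a \code{\link{SweepResult}} with axis "signal_length".
#' @export
runSignalLengthSweep <- function(config = list()) {
  cfg <- modifyList(list(
    lengths = 5:9, clb = clbParams(),
    signalAmplitude = rayleighSignalSpec()@amplitude,
    nTrainPerClass = 300L, nValPerClass = 100L, nTestPerClass = 200L,
    crop = 32L, lambdaGrid = 10^seq(-9, -4), choRidge = 1e-8, seed = 1L,
    srModel = NULL
  ), config)
  rows <- data.frame()
  details <- list()
  for (L in cfg$lengths) {
    specs <- list(clb = cfg$clb,
                  signal = rayleighSignalSpec(L, amplitude =
                                                cfg$signalAmplitude))
    seedL <- seedStream(cfg$seed, "misc", offset = L)
    ntot <- cfg$nTrainPerClass + cfg$nValPerClass + cfg$nTestPerClass
    ens <- buildTaskEnsembles("rayleigh", ntot, specs, seed = seedL)
    itr <- seq_len(2 * cfg$nTrainPerClass)
    iva <- 2 * cfg$nTrainPerClass + seq_len(2 * cfg$nValPerClass)
    ite <- 2 * (cfg$nTrainPerClass + cfg$nValPerClass) +
      seq_len(2 * cfg$nTestPerClass)
    sets <- list(HR = list(ens$hr[itr], ens$hr[iva], ens$hr[ite]),
                 LR = list(ens$lr[itr], ens$lr[iva], ens$lr[ite]))
    if (!is.null(cfg$srModel)) {
      sets$SR <- list(applySR(cfg$srModel, ens$lr[itr]),
                      applySR(cfg$srModel, ens$lr[iva]),
                      applySR(cfg$srModel, ens$lr[ite]))
    }
    for (rc in names(sets)) {
      s <- sets[[rc]]
      res <- .linear_observer_aucs(s[[1]], s[[2]], s[[3]], cfg$crop,
                                   cfg$lambdaGrid, cfg$choRidge)
      iq <- if (rc == "HR") {
        new("IQMetrics", ensembleMSE = 0, psnr = Inf, ssim = 1,
            peak = max(ens$hr@images), nImages = length(ite))
      } else {
        iqMetrics(ens$hr[ite], s[[3]])
      }
      for (obs in c("RHO", "CHO")) {
        rows <- rbind(rows, cbind(
          data.frame(level = L, resolution = rc, observer = obs,
                     lambda = ifelse(obs == "RHO", res$lambda, NA)),
          .roc_row(res[[obs]]), .iq_row(iq), seed = seedL))
      }
    }
  }
  new("SweepResult", axis = "signal_length", table = rows,
      details = details)
}

#' SR network depth sweep for the Rayleigh task
#'
#' Trains an SR network per depth on a fixed simulated dataset, evaluates
#' ensemble MSE and the RHO/CHO AUC on the SR images, and computes the
#' singular-value spectrum of the SR-image covariance together with a
#' tail-mass statistic (fraction of the spectrum mass beyond the leading
#' modes), which quantifies how ill-conditioned the SR covariance becomes.
#'
#' @param config list with components \code{depths} (default c(2, 4, 6)),
#'   \code{signalLength}, \code{clb}, \code{signalAmplitude},
#'   \code{nTrainPerClass}, \code{nValPerClass}, \code{nTestPerClass},
#'   \code{crop}, \code{lambdaGrid}, \code{choRidge}, \code{training} (a
#'   \code{TrainingConfig}; the default \code{epochsPerDepth = 0} gives
#'   every depth the same fixed budget, a positive value adds epochs per
#'   layer), \code{patchSize}, \code{nPatches}, \code{hiddenChannels},
#'   \code{tailRank}, \code{seed}.
#' @return a \code{\link{SweepResult}} with axis "n_layers"; per-depth
#'   spectra in \code{details}.
#' @export
runDepthSweep <- function(config = list()) {
  cfg <- modifyList(list(
    depths = c(2L, 4L, 6L), signalLength = 7L, clb = clbParams(),
    signalAmplitude = rayleighSignalSpec()@amplitude,
    nTrainPerClass = 250L, nValPerClass = 75L, nTestPerClass = 150L,
    crop = 32L, lambdaGrid = 10^seq(-9, -4), choRidge = 1e-8,
    training = trainingConfig(maxEpochs = 8L, learningRate = 4e-3,
                              batchSize = 16L),
    epochsPerDepth = 0L,
    patchSize = 24L, nPatches = 1600L, hiddenChannels = 16L,
    tailRank = 10L, seed = 1L
  ), config)
  specs <- list(clb = cfg$clb,
                signal = rayleighSignalSpec(cfg$signalLength,
                                            amplitude = cfg$signalAmplitude))
  ntot <- cfg$nTrainPerClass + cfg$nValPerClass + cfg$nTestPerClass
  ens <- buildTaskEnsembles("rayleigh", ntot, specs, seed = cfg$seed)
  itr <- seq_len(2 * cfg$nTrainPerClass)
  iva <- 2 * cfg$nTrainPerClass + seq_len(2 * cfg$nValPerClass)
  ite <- 2 * (cfg$nTrainPerClass + cfg$nValPerClass) +
    seq_len(2 * cfg$nTestPerClass)
  patches <- extractPatches(ens$lr@images[, , itr, drop = FALSE],
                            ens$hr@images[, , itr, drop = FALSE],
                            cfg$patchSize, cfg$nPatches,
                            seed = seedStream(cfg$seed, "training"))
  rows <- data.frame()
  details <- list()
  for (d in cfg$depths) {
    sr <- buildSRCNN(srNetworkSpec(d, hiddenChannels = cfg$hiddenChannels),
                     seed = seedStream(cfg$seed, "init", offset = d))
    # deeper networks get proportionally more epochs so that every depth
    # reaches its validation plateau before evaluation
    tcfg <- cfg$training
    tcfg@maxEpochs <- tcfg@maxEpochs + cfg$epochsPerDepth * as.integer(d)
    sr <- trainSR(sr, patches$lr, patches$hr, cfg = tcfg)
    srSets <- list(applySR(sr, ens$lr[itr]), applySR(sr, ens$lr[iva]),
                   applySR(sr, ens$lr[ite]))
    res <- .linear_observer_aucs(srSets[[1]], srSets[[2]], srSets[[3]],
                                 cfg$crop, cfg$lambdaGrid, cfg$choRidge)
    iq <- iqMetrics(ens$hr[ite], srSets[[3]])
    cl <- .class_split(srSets[[1]])
    model <- ensureSVD(fitCovarianceModel(cl$h0, cl$h1, crop = cfg$crop))
    sv <- model@svd$d
    tail_mass <- sum(sv[-seq_len(min(cfg$tailRank, length(sv)))]) / sum(sv)
    for (obs in c("RHO", "CHO")) {
      rows <- rbind(rows, cbind(
        data.frame(level = d, resolution = "SR", observer = obs,
                   lambda = ifelse(obs == "RHO", res$lambda, NA),
                   tailMass = tail_mass),
        .roc_row(res[[obs]]), .iq_row(iq), seed = cfg$seed))
    }
    details[[as.character(d)]] <- list(singularValues = sv,
                                       tailMass = tail_mass,
                                       history = sr@history)
  }
  new("SweepResult", axis = "n_layers", table = rows, details = details)
}

#' Observer capacity / training-set-size sweep for the MC task
#'
#' Trains a residual-network observer per (capacity, training size,
#' resolution class) cell on the MC-cluster task and reports test AUC per
#' cell.
#'
#' @param config list with components \code{blocks} (default c(2, 6)),
#'   \code{nTrainGrid} (per-class training sizes), \code{clb}, \code{mc},
#'   \code{nValPerClass}, \code{nTestPerClass}, \code{inputSize},
#'   \code{channels}, \code{training} (a \code{TrainingConfig}),
#'   \code{srModel} (trained SRCNN; NULL skips the SR class),
#'   \code{resolutions} (subset of HR/LR/SR), \code{seed}.
#' @return a \code{\link{SweepResult}} with axis "n_train".
#' @export
runCapacitySweep <- function(config = list()) {
  cfg <- modifyList(list(
    blocks = c(2L, 6L), nTrainGrid = c(200L, 400L),
    clb = clbParams(), mc = mcClusterSpec(),
    nValPerClass = 100L, nTestPerClass = 200L,
    inputSize = 64L, channels = 8L,
    training = trainingConfig(maxEpochs = 6L, learningRate = 5e-4),
    srModel = NULL, resolutions = c("LR", "SR"), seed = 1L
  ), config)
  nmax <- max(cfg$nTrainGrid)
  ntot <- nmax + cfg$nValPerClass + cfg$nTestPerClass
  ens <- buildTaskEnsembles("mc", ntot,
                            list(clb = cfg$clb, mc = cfg$mc),
                            seed = cfg$seed, keepNoiseless = TRUE)
  iva <- 2 * nmax + seq_len(2 * cfg$nValPerClass)
  ite <- 2 * (nmax + cfg$nValPerClass) + seq_len(2 * cfg$nTestPerClass)
  sets <- list(HR = ens$hr, LR = ens$lr)
  if (!is.null(cfg$srModel)) sets$SR <- applySR(cfg$srModel, ens$lr)
  sets <- sets[intersect(names(sets), cfg$resolutions)]
  rows <- data.frame()
  for (rc in names(sets)) {
    full <- sets[[rc]]
    for (ntr in cfg$nTrainGrid) {
      itr <- seq_len(2 * ntr)
      for (nb in cfg$blocks) {
        obs <- buildResnetObserver(
          observerNetworkSpec(nb, inputSize = cfg$inputSize,
                              channels = cfg$channels),
          seed = seedStream(cfg$seed, "init", offset = 100 * nb + ntr))
        obs <- trainObserver(obs, full[itr], full[iva], cfg$training)
        roc <- deLongCI(scoreObserver(obs, full[ite]))
        rows <- rbind(rows, cbind(
          data.frame(level = ntr, nBlocks = nb, resolution = rc,
                     observer = "resnet"),
          .roc_row(roc), seed = cfg$seed))
      }
    }
  }
  new("SweepResult", axis = "n_train", table = rows, details = list())
}
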