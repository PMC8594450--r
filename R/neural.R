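## Reduced-scale trainable components: the SRCNN family for
## super-resolution and residual-network observers for learned detection.
## The networks run on a small im2col convolution engine (src/convnet.cpp);
## initialization and Adam optimization live here so that training is fully
## reproducible from R's RNG.

#' Specification of a feed-forward SR network
#'
#' A chain of \code{nLayers} convolutions with pointwise rectifiers between
#' layers (none after the last), same padding: 9x9 kernel in the first
#' layer, 5x5 in the others, 32 hidden channels, single-channel output.
#'
#' @param nLayers number of convolutional layers (2..8).
#' @param firstFilter first-layer kernel side.
#' @param hiddenFilter kernel side of the remaining layers.
#' @param hiddenChannels hidden channel count.
#' @return a spec list.
#' @export
srNetworkSpec <- function(nLayers = 3L, firstFilter = 9L, hiddenFilter = 5L,
                          hiddenChannels = 32L) {
  if (nLayers < 2) stop("nLayers must be >= 2")
  list(kind = "srcnn", nLayers = as.integer(nLayers),
       firstFilter = as.integer(firstFilter),
       hiddenFilter = as.integer(hiddenFilter),
       hiddenChannels = as.integer(hiddenChannels),
       kernels = c(firstFilter, rep(hiddenFilter, nLayers - 1L)),
       channels = c(1L, rep(hiddenChannels, nLayers - 1L), 1L))
}

#' Specification of a residual-network observer
#'
#' Architecture: 3x3 conv stem (1 -> \code{channels}), rectifier, 2x2
#' average pool, \code{nBlocks} residual blocks (two 3x3 convs with a
#' rectifier and an additive skip), global average pooling and a linear
#' head emitting one score per image; a parallel linear-template path on
#' the raw input supports warm starts from a linear-observer template.
#'
#' @param nBlocks number of residual blocks.
#' @param inputSize input image side, pixels (must be even).
#' @param channels feature channels.
#' @param pool stem pooling factor (1 or 2).
#' @return a spec list.
#' @export
observerNetworkSpec <- function(nBlocks = 2L, inputSize = 64L,
                                channels = 16L, pool = 2L) {
  if (nBlocks < 1) stop("nBlocks must be positive")
  if (pool == 2 && inputSize %% 2 != 0) {
    stop("inputSize must be even when pool = 2")
  }
  list(kind = "resnet_observer", nBlocks = as.integer(nBlocks),
       inputSize = as.integer(inputSize), channels = as.integer(channels),
       pool = as.integer(pool))
}

#' Training configuration
#'
#' @param nTrain,nVal training / validation sample counts (used by the
#'   drivers when they generate data; training functions consume whatever
#'   data they are given).
#' @param batchSize mini-batch size.
#' @param learningRate Adam step size.
#' @param maxEpochs epoch budget.
#' @param seed RNG seed for shuffling and on-the-fly noise.
#' @param semionlineNoise re-draw measurement noise each epoch from stored
#'   noiseless composites (observer training).
#' @param flipAugment fourfold flip augmentation (observer training).
#' @param earlySelection keep the best-validation checkpoint.
#' @return a \code{\link{TrainingConfig}}.
#' @export
trainingConfig <- function(nTrain = 2000L, nVal = 200L, batchSize = 32L,
                           learningRate = 1e-3, maxEpochs = 10L, seed = 1L,
                           semionlineNoise = FALSE, flipAugment = FALSE,
                           earlySelection = TRUE) {
  new("TrainingConfig", nTrain = as.integer(nTrain), nVal = as.integer(nVal),
      batchSize = as.integer(batchSize), learningRate = learningRate,
      maxEpochs = as.integer(maxEpochs), optimizer = "adam",
      seed = as.integer(seed), semionlineNoise = semionlineNoise,
      flipAugment = flipAugment, earlySelection = earlySelection)
}

## ---- parameter trees and Adam ------------------------------------------

.tree_map <- function(f, ...) {
  trees <- list(...)
  if (is.list(trees[[1]])) {
    out <- vector("list", length(trees[[1]]))
    names(out) <- names(trees[[1]])
    for (i in seq_along(out)) {
      out[[i]] <- do.call(.tree_map, c(list(f), lapply(trees, `[[`, i)))
    }
    out
  } else {
    do.call(f, trees)
  }
}

.tree_zeros <- function(p) .tree_map(function(x) x * 0, p)

.adam_step <- function(params, grads, state, lr, t, b1 = 0.9, b2 = 0.999,
                       eps = 1e-8) {
  state$m <- .tree_map(function(m, g) b1 * m + (1 - b1) * g, state$m, grads)
  state$v <- .tree_map(function(v, g) b2 * v + (1 - b2) * g^2, state$v,
                       grads)
  c1 <- 1 / (1 - b1^t)
  c2 <- 1 / (1 - b2^t)
  params <- .tree_map(function(p, m, v) p - lr * (m * c1) /
                        (sqrt(v * c2) + eps),
                      params, state$m, state$v)
  list(params = params, state = state)
}

#' Count trainable parameters of a model
#'
#' @param model a \code{\link{ConvNetModel}}.
#' @return integer parameter count.
#' @export
countParameters <- function(model) {
  sum(unlist(rapply(model@params, length, how = "unlist")))
}

## ---- SRCNN --------------------------------------------------------------

#' Build an SR network
#'
#' Two deterministic (seeded) initialization schemes are available.
#' \code{"identity"} (the default) starts the network as an approximate
#' identity map: the first channel carries the input through every layer
#' (centre-tap delta kernels) with small Gaussian perturbations elsewhere,
#' so the initial output roughly equals the input and short training
#' budgets refine from the low-resolution image rather than from scratch.
#' \code{"he"} is plain He-scaled Gaussian initialization.
#'
#' @param spec a spec from \code{\link{srNetworkSpec}}.
#' @param seed integer seed.
#' @param init "identity" or "he".
#' @return an untrained \code{\link{ConvNetModel}}.
#' @examples
#' m <- buildSRCNN(srNetworkSpec(3L), seed = 1)
#' countParameters(m)  # 29057
#' @export
buildSRCNN <- function(spec, seed = 1L, init = c("identity", "he")) {
  if (!identical(spec$kind, "srcnn")) stop("spec must come from srNetworkSpec")
  init <- match.arg(init)
  L <- spec$nLayers
  withSeed(seed, {
    W <- vector("list", L)
    b <- vector("list", L)
    for (l in seq_len(L)) {
      k <- spec$kernels[l]
      cin <- spec$channels[l]
      cout <- spec$channels[l + 1]
      fan <- cin * k * k
      sdv <- sqrt(2 / fan)
      if (l == L) sdv <- sdv / 10
      if (init == "identity") sdv <- sdv / 20
      W[[l]] <- matrix(rnorm(cout * fan, 0, sdv), cout, fan)
      b[[l]] <- numeric(cout)
      if (init == "identity") {
        # channel 1 passes the image through every rectifier: a +4 bias
        # shift keeps the standardized intensities positive, removed at
        # the output
        ctr_idx <- 1 + cin * ((k %/% 2) + k * (k %/% 2))
        W[[l]][1, ctr_idx] <- W[[l]][1, ctr_idx] + 1
        if (l == 1) b[[l]][1] <- 4
        if (l == L) b[[l]][1] <- b[[l]][1] - 4
      }
    }
    new("ConvNetModel", kind = "srcnn", spec = spec,
        params = list(W = W, b = b), trained = FALSE,
        provenance = list(seed = seed, init = init))
  })
}

## forward pass with the model's intensity normalization applied: the
## network operates on standardized intensities ((x - mu)/sd, fixed at the
## start of training), and outputs are mapped back to the image scale
.sr_forward <- function(model, X, target = NULL, want_grad = FALSE) {
  nrm <- model@spec$norm
  if (!is.null(nrm)) {
    X <- (X - nrm$mu) / nrm$sd
    if (!is.null(target)) target <- (target - nrm$mu) / nrm$sd
  }
  res <- .cnn_sr_batch(X, model@params$W, model@params$b,
                       model@spec$kernels, want_grad, target)
  if (!is.null(nrm)) res$out <- res$out * nrm$sd + nrm$mu
  res
}

#' Train an SR network with an MSE loss
#'
#' Minimizes the mean squared error between the network output on LR inputs
#' and the HR targets over mini-batches (Adam).  The checkpoint with the
#' best validation loss is returned when \code{earlySelection} is set.
#'
#' @param model an untrained (or pre-trained) SRCNN \code{ConvNetModel}.
#' @param lrTrain,hrTrain paired training input/target arrays (H, W, N).
#' @param lrVal,hrVal paired validation arrays; NULL reuses a held-out
#'   tail fraction of the training pairs.
#' @param cfg a \code{\link{TrainingConfig}}.
#' @return the trained \code{ConvNetModel} with a per-epoch history.
#' @export
trainSR <- function(model, lrTrain, hrTrain, lrVal = NULL, hrVal = NULL,
                    cfg = trainingConfig()) {
  if (model@kind != "srcnn") stop("model must be an SRCNN")
  if (!all(dim(lrTrain) == dim(hrTrain))) stop("paired array shapes differ")
  if (is.null(lrVal)) {
    nv <- max(2L, floor(dim(lrTrain)[3] * 0.1))
    idx <- seq_len(dim(lrTrain)[3])
    vi <- tail(idx, nv)
    lrVal <- lrTrain[, , vi, drop = FALSE]
    hrVal <- hrTrain[, , vi, drop = FALSE]
    lrTrain <- lrTrain[, , -vi, drop = FALSE]
    hrTrain <- hrTrain[, , -vi, drop = FALSE]
  }
  if (is.null(model@spec$norm)) {
    # fix the intensity standardization from the training targets
    model@spec$norm <- list(mu = mean(hrTrain), sd = max(sd(hrTrain), 1e-12))
  }
  N <- dim(lrTrain)[3]
  params <- model@params
  state <- list(m = .tree_zeros(params), v = .tree_zeros(params))
  best <- list(loss = Inf, params = params)
  hist <- data.frame()
  t_step <- 0L
  withSeed(cfg@seed, {
    for (epoch in seq_len(cfg@maxEpochs)) {
      perm <- sample.int(N)
      tr_loss <- 0
      nb <- 0
      for (s in seq(1, N, by = cfg@batchSize)) {
        idx <- perm[s:min(s + cfg@batchSize - 1L, N)]
        model@params <- params
        res <- .sr_forward(model, lrTrain[, , idx, drop = FALSE],
                           hrTrain[, , idx, drop = FALSE], want_grad = TRUE)
        grads <- list(W = res$gW, b = res$gb)
        t_step <- t_step + 1L
        up <- .adam_step(params, grads, state, cfg@learningRate, t_step)
        params <- up$params
        state <- up$state
        tr_loss <- tr_loss + res$loss
        nb <- nb + 1
      }
      model@params <- params
      vres <- .sr_forward(model, lrVal, hrVal, want_grad = FALSE)
      hist <- rbind(hist, data.frame(epoch = epoch,
                                     trainLoss = tr_loss / nb,
                                     valLoss = vres$loss))
      if (vres$loss < best$loss) best <- list(loss = vres$loss,
                                              params = params)
    }
  })
  model@params <- if (cfg@earlySelection) best$params else params
  model@trained <- TRUE
  model@history <- hist
  model@provenance <- c(model@provenance,
                        list(trainSeed = cfg@seed,
                             nTrain = N, bestValLoss = best$loss))
  model
}

#' Super-resolve an ensemble
#'
#' @param model a trained SRCNN \code{ConvNetModel}.
#' @param ens an \code{\link{ImagingEnsemble}} (typically LR).
#' @param chunk forward-pass batch size.
#' @return an \code{\link{ImagingEnsemble}} with resolution class "SR".
#' @export
applySR <- function(model, ens, chunk = 64L) {
  if (model@kind != "srcnn") stop("model must be an SRCNN")
  X <- ens@images
  N <- dim(X)[3]
  out <- array(0, dim = dim(X))
  for (s in seq(1, N, by = chunk)) {
    idx <- s:min(s + chunk - 1L, N)
    out[, , idx] <- .sr_forward(model, X[, , idx, drop = FALSE])$out
  }
  gs <- ens@generationSpec
  gs$srModel <- list(spec = model@spec, provenance = model@provenance,
                     trained = model@trained)
  if (!model@trained) {
    gs$srModel$warning <- "applied an untrained SR model"
  }
  new("ImagingEnsemble", images = out, labels = ens@labels,
      resolutionClass = "SR", generationSpec = gs)
}

## ---- residual-network observer -----------------------------------------

#' Build a residual-network observer
#'
#' Convolutional weights use He-scaled Gaussian initialization.  When a
#' warm-start template is supplied, the parallel linear path is set to the
#' template weights and the convolutional head is zeroed, so the untrained
#' observer scores images exactly like the linear template; training then
#' refines both paths.  Without a warm start the linear path is frozen at
#' zero, so observer capacity is determined by the residual blocks alone.
#'
#' @param spec a spec from \code{\link{observerNetworkSpec}}.
#' @param warmStart optional \code{\link{LinearTemplate}} whose weight
#'   length equals \code{inputSize^2}.
#' @param seed integer seed.
#' @return an untrained \code{\link{ConvNetModel}}.
#' @export
buildResnetObserver <- function(spec, warmStart = NULL, seed = 1L) {
  if (!identical(spec$kind, "resnet_observer")) {
    stop("spec must come from observerNetworkSpec")
  }
  C <- spec$channels
  npix <- spec$inputSize^2
  withSeed(seed, {
    mk <- function(cout, cin, k) {
      matrix(rnorm(cout * cin * k * k, 0, sqrt(2 / (cin * k * k))),
             cout, cin * k * k)
    }
    blocks <- vector("list", spec$nBlocks)
    for (j in seq_len(spec$nBlocks)) {
      blocks[[j]] <- list(W1 = mk(C, C, 3L), b1 = numeric(C),
                          W2 = mk(C, C, 3L) * 0.1, b2 = numeric(C))
    }
    params <- list(stem_W = mk(C, 1L, 3L), stem_b = numeric(C),
                   blocks = blocks,
                   head_w = rnorm(C, 0, 0.01), head_wm = rnorm(C, 0, 0.01),
                   head_b = 0, lin_w = numeric(npix))
    if (!is.null(warmStart)) {
      if (length(warmStart@weights) != npix) {
        stop("warm-start template length does not match inputSize^2")
      }
      params$lin_w <- warmStart@weights
      params$head_w <- numeric(C)
      params$head_wm <- numeric(C)
    }
    # the linear path is trainable only for warm-started observers; for
    # from-scratch observers capacity is carried by the residual blocks
    spec$useLinearPath <- !is.null(warmStart)
    new("ConvNetModel", kind = "resnet_observer", spec = spec,
        params = params, trained = FALSE,
        provenance = list(seed = seed,
                          warmStart = !is.null(warmStart)))
  })
}

.observer_crop <- function(model, X) {
  sz <- model@spec$inputSize
  if (dim(X)[1] != sz) {
    s <- floor((dim(X)[1] - sz) / 2) + 1L
    X <- X[s:(s + sz - 1L), s:(s + sz - 1L), , drop = FALSE]
  }
  X
}

.observer_forward <- function(model, X, y = NULL, want_grad = FALSE) {
  X <- .observer_crop(model, X)
  nrm <- model@spec$norm
  if (!is.null(nrm)) X <- (X - nrm$mu) / nrm$sd
  .cnn_resnet_batch(X, model@params, model@spec$pool, want_grad, y)
}

.flip_augment <- function(X, y) {
  n <- dim(X)[1]
  Xs <- list(X,
             X[n:1, , , drop = FALSE],
             X[, n:1, , drop = FALSE],
             X[n:1, n:1, , drop = FALSE])
  list(X = array(unlist(Xs), dim = c(n, n, 4 * dim(X)[3])),
       y = rep(y, times = 4))
}

#' Train a residual-network observer with binary cross-entropy
#'
#' With \code{semionlineNoise} the measurement-noise component of every
#' training image is re-drawn each epoch from the stored noiseless
#' composites (the ensemble must have been built with
#' \code{keepNoiseless = TRUE}); for upsampled-LR ensembles the fresh noise
#' is drawn on the stored (already upsampled) grid.  The checkpoint with
#' the best validation AUC is returned when \code{earlySelection} is set.
#'
#' @param model a \code{ConvNetModel} from
#'   \code{\link{buildResnetObserver}}.
#' @param trainEns,valEns \code{\link{ImagingEnsemble}}s with both classes.
#' @param cfg a \code{\link{TrainingConfig}}.
#' @return the trained model with a per-epoch history.
#' @export
trainObserver <- function(model, trainEns, valEns, cfg = trainingConfig()) {
  if (model@kind != "resnet_observer") {
    stop("model must be a resnet observer")
  }
  labs <- trainEns@labels
  if (length(unique(labs)) < 2) stop("training data must contain both classes")
  y <- as.numeric(labs == "H1")
  Xtr <- .observer_crop(model, trainEns@images)
  noiseless <- NULL
  nspec <- NULL
  if (cfg@semionlineNoise) {
    gs <- trainEns@generationSpec
    key <- if (identical(trainEns@resolutionClass, "HR")) "noiselessHR"
           else "noiselessLR"
    noiseless <- gs[[key]]
    nspec <- gs$noise
    if (is.null(noiseless) || is.null(nspec)) {
      stop("semionline training needs an ensemble built with keepNoiseless = TRUE")
    }
    noiseless <- .observer_crop(model, noiseless)
  }
  yv <- as.numeric(valEns@labels == "H1")
  Xval <- .observer_crop(model, valEns@images)

  if (is.null(model@spec$norm)) {
    # standardize inputs from the training images; fold the change of
    # variables into the linear path so warm-start scores are unchanged
    mu <- mean(Xtr)
    sdv <- max(sd(Xtr), 1e-12)
    model@spec$norm <- list(mu = mu, sd = sdv)
    model@params$head_b <- model@params$head_b +
      mu * sum(model@params$lin_w)
    model@params$lin_w <- model@params$lin_w * sdv
  }
  nrm <- model@spec$norm
  Xtr <- (Xtr - nrm$mu) / nrm$sd
  Xval <- (Xval - nrm$mu) / nrm$sd
  if (!is.null(noiseless)) noiseless <- (noiseless - nrm$mu) / nrm$sd

  params <- model@params
  state <- list(m = .tree_zeros(params), v = .tree_zeros(params))
  best <- list(auc = -Inf, params = params)
  hist <- data.frame()
  t_step <- 0L
  withSeed(cfg@seed, {
    for (epoch in seq_len(cfg@maxEpochs)) {
      Xe <- Xtr
      if (cfg@semionlineNoise) {
        # fresh noise on the standardized scale
        Xe <- noiseless + array(.draw_noise(length(noiseless), nspec),
                                dim = dim(noiseless)) / nrm$sd
      }
      ye <- y
      if (cfg@flipAugment) {
        aug <- .flip_augment(Xe, y)
        Xe <- aug$X
        ye <- aug$y
      }
      N <- dim(Xe)[3]
      perm <- sample.int(N)
      tr_loss <- 0
      nb <- 0
      for (s in seq(1, N, by = cfg@batchSize)) {
        idx <- perm[s:min(s + cfg@batchSize - 1L, N)]
        model@params <- params
        res <- .cnn_resnet_batch(Xe[, , idx, drop = FALSE], params,
                                 model@spec$pool, TRUE, ye[idx])
        if (!isTRUE(model@spec$useLinearPath)) {
          res$grads$lin_w[] <- 0
        }
        t_step <- t_step + 1L
        up <- .adam_step(params, res$grads, state, cfg@learningRate, t_step)
        params <- up$params
        state <- up$state
        tr_loss <- tr_loss + res$loss
        nb <- nb + 1
      }
      model@params <- params
      vres <- .cnn_resnet_batch(Xval, params, model@spec$pool, FALSE, yv)
      vauc <- empiricalAUC(new("ScoreSet",
                               scoresH0 = vres$scores[yv == 0],
                               scoresH1 = vres$scores[yv == 1]))
      hist <- rbind(hist, data.frame(epoch = epoch,
                                     trainLoss = tr_loss / nb,
                                     valLoss = vres$loss, valAUC = vauc))
      if (vauc > best$auc) best <- list(auc = vauc, params = params)
    }
  })
  model@params <- if (cfg@earlySelection) best$params else params
  model@trained <- TRUE
  model@history <- hist
  model@provenance <- c(model@provenance,
                        list(trainSeed = cfg@seed, bestValAUC = best$auc))
  model
}

#' Score an ensemble with a learned observer
#'
#' @param model a (trained) observer \code{ConvNetModel}.
#' @param ens an \code{\link{ImagingEnsemble}}.
#' @param observerId label for the score set.
#' @return a \code{\link{ScoreSet}}.
#' @export
scoreObserver <- function(model, ens, observerId = "resnet") {
  res <- .observer_forward(model, ens@images)
  labs <- ens@labels
  new("ScoreSet", scoresH0 = res$scores[labs == "H0"],
      scoresH1 = res$scores[labs == "H1"], observerId = observerId)
}

#' Extract aligned random patches from paired arrays
#'
#' Used to train SR networks on sub-images of the simulated pairs.
#'
#' @param lrArr,hrArr paired arrays (H, W, N) of identical shape.
#' @param patchSize patch side, pixels.
#' @param nPatches number of patches.
#' @param seed integer seed.
#' @return list of paired arrays \code{lr}, \code{hr} of shape
#'   (patchSize, patchSize, nPatches).
#' @export
extractPatches <- function(lrArr, hrArr, patchSize, nPatches, seed = 1L) {
  if (!all(dim(lrArr) == dim(hrArr))) stop("paired array shapes differ")
  H <- dim(lrArr)[1]
  N <- dim(lrArr)[3]
  if (patchSize > H) stop("patchSize exceeds the image side")
  withSeed(seed, {
    lr <- array(0, dim = c(patchSize, patchSize, nPatches))
    hr <- array(0, dim = c(patchSize, patchSize, nPatches))
    for (i in seq_len(nPatches)) {
      img <- sample.int(N, 1)
      x <- sample.int(H - patchSize + 1L, 1)
      y <- sample.int(H - patchSize + 1L, 1)
      lr[, , i] <- lrArr[y:(y + patchSize - 1L), x:(x + patchSize - 1L), img]
      hr[, , i] <- hrArr[y:(y + patchSize - 1L), x:(x + patchSize - 1L), img]
    }
    list(lr = lr, hr = hr)
  })
}
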