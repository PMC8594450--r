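## Degradation operators, noise model and ensemble assembly.

#' Construct a degradation specification
#'
#' Defaults per task: the Rayleigh task uses blur sigma = 1.5 px with no
#' resampling; the MC task uses blur sigma = 1.5 px, decimation by 2, and
#' bilinear upsampling back to the HR grid (after noise).
#'
#' @param task "rayleigh" or "mc".
#' @param blurSigma Gaussian blur std, pixels.
#' @param downsampleFactor integer decimation factor.
#' @param upsampleBack upsample the LR image back to the HR grid.
#' @return a \code{\link{DegradationSpec}}.
#' @export
degradationSpec <- function(task = c("rayleigh", "mc"), blurSigma = 1.5,
                            downsampleFactor = NULL, upsampleBack = NULL) {
  task <- match.arg(task)
  if (is.null(downsampleFactor)) {
    downsampleFactor <- if (task == "mc") 2L else 1L
  }
  if (is.null(upsampleBack)) upsampleBack <- task == "mc"
  new("DegradationSpec", blurSigma = blurSigma,
      downsampleFactor = as.integer(downsampleFactor),
      upsampleBack = upsampleBack, task = task)
}

#' Construct a noise specification
#'
#' Defaults per task: sigma_p = 0.013, sigma_g = 0.35 for the Rayleigh task
#' and sigma_p = 1e-4, sigma_g = 1e-3 for the MC task, both with internal
#' Poisson rate 10.
#'
#' @param task "rayleigh" or "mc".
#' @param poissonScale scaled-Poisson std sigma_p.
#' @param gaussianStd Gaussian std sigma_g.
#' @param poissonRate internal Poisson rate lambda_0.
#' @return a \code{\link{NoiseSpec}}.
#' @export
noiseSpec <- function(task = c("rayleigh", "mc"), poissonScale = NULL,
                      gaussianStd = NULL, poissonRate = 10) {
  task <- match.arg(task)
  if (is.null(poissonScale)) {
    poissonScale <- if (task == "mc") 1e-4 else 0.013
  }
  if (is.null(gaussianStd)) gaussianStd <- if (task == "mc") 1e-3 else 0.35
  new("NoiseSpec", poissonScale = poissonScale, gaussianStd = gaussianStd,
      poissonRate = poissonRate)
}

#' Gaussian blur of an image
#'
#' Convolution with a normalized sampled Gaussian kernel truncated at
#' +/- 4 sigma, mirror boundary.  \code{sigma = 0} is the identity.
#'
#' @param img numeric matrix or \code{\link{ObjectImage}}.
#' @param sigma blur std, pixels (>= 0).
#' @return a matrix (or \code{ObjectImage} matching the input type).
#' @export
gaussianBlur <- function(img, sigma) {
  if (sigma < 0) stop("sigma must be >= 0")
  isObj <- is(img, "ObjectImage")
  px <- if (isObj) img@pixels else img
  out <- .gauss_filter(px, sigma, -1L)
  if (isObj) {
    img@pixels <- out
    img
  } else {
    out
  }
}

#' Resample an image by an integer factor
#'
#' Downsampling takes every \code{factor}-th pixel (the caller is expected
#' to have applied any anti-alias blur); upsampling is bilinear with
#' pixel-centre alignment.
#'
#' @param img numeric matrix.
#' @param factor integer factor >= 1.
#' @param direction "down" or "up".
#' @return the resampled matrix.
#' @export
resampleImage <- function(img, factor, direction = c("down", "up")) {
  direction <- match.arg(direction)
  factor <- as.integer(factor)
  if (factor < 1) stop("factor must be >= 1")
  if (factor == 1) return(img)
  if (direction == "down") {
    if (nrow(img) %% factor != 0 || ncol(img) %% factor != 0) {
      stop("image side not divisible by the downsampling factor")
    }
    img[seq(1, nrow(img), by = factor), seq(1, ncol(img), by = factor),
        drop = FALSE]
  } else {
    .bilinear_upsample(img, factor)
  }
}

#' Add mixed Poisson-Gaussian noise
#'
#' Adds \eqn{n = \sigma_p (P - \lambda_0)/\sqrt{\lambda_0} + \sigma_g Z}
#' per pixel with P ~ Poisson(lambda_0) and Z standard normal, independent
#' across pixels: zero-mean noise with per-pixel standard deviation
#' \eqn{\sqrt{\sigma_p^2 + \sigma_g^2}}, independent of the image content.
#'
#' @param img numeric matrix.
#' @param spec a \code{\link{NoiseSpec}}.
#' @param seed optional integer seed (local to this call).
#' @return the noisy matrix.
#' @export
addMixedNoise <- function(img, spec, seed = NULL) {
  validObject(spec)
  withSeed(seed, img + .draw_noise(length(img), spec))
}

.draw_noise <- function(npix, spec) {
  n <- numeric(npix)
  if (spec@poissonScale > 0) {
    lam <- spec@poissonRate
    n <- n + spec@poissonScale * (rpois(npix, lam) - lam) / sqrt(lam)
  }
  if (spec@gaussianStd > 0) n <- n + spec@gaussianStd * rnorm(npix)
  n
}

#' Build paired HR/LR ensembles for a detection task
#'
#' Generates \code{nPerClass} class-balanced objects, then forms the HR
#' ensemble (object + noise) and the LR ensemble (degraded object + noise,
#' with noise drawn independently of the HR noise).  For the Rayleigh task
#' the degradation is a Gaussian blur on the HR grid; for the MC task it is
#' blur, decimation by 2, noise at the LR grid, then bilinear upsampling
#' back to the HR grid.  Images are shuffled with a recorded permutation.
#'
#' @param task "rayleigh" or "mc".
#' @param nPerClass images per class.
#' @param specs list with components \code{clb} (\code{CLBParams}),
#'   \code{degradation} (\code{DegradationSpec}), \code{noise}
#'   (\code{NoiseSpec}) and, per task, \code{signal}
#'   (\code{RayleighSignalSpec}; its \code{signalLength} may be a vector to
#'   mix lengths) or \code{mc} (\code{MCClusterSpec}).  Missing components
#'   take the task defaults.
#' @param seed master seed; all internal draws derive from named streams of
#'   this seed.
#' @param keepNoiseless store the noiseless composites in the generation
#'   spec (needed for semionline observer training).
#' @return list with elements \code{hr} and \code{lr}
#'   (\code{\link{ImagingEnsemble}}s).
#' @examples
#' ens <- buildTaskEnsembles("rayleigh", 3,
#'   specs = list(clb = clbParams(fieldSize = 64L, meanClusters = 40)),
#'   seed = 7)
#' ens$hr
#' @export
buildTaskEnsembles <- function(task = c("rayleigh", "mc"), nPerClass,
                               specs = list(), seed = 1L,
                               keepNoiseless = FALSE) {
  task <- match.arg(task)
  if (nPerClass < 1) stop("nPerClass must be >= 1")
  clb <- specs$clb %||% clbParams()
  deg <- specs$degradation %||% degradationSpec(task)
  noi <- specs$noise %||% noiseSpec(task)
  n <- clb@fieldSize
  N <- 2L * as.integer(nPerClass)
  labs <- rep(c("H0", "H1"), each = nPerClass)

  sigLens <- NULL
  sigImgs <- NULL
  mcspec <- NULL
  if (task == "rayleigh") {
    sig <- specs$signal %||% rayleighSignalSpec()
    sigLens <- rep_len(sig@signalLength, nPerClass)
    uls <- sort(unique(sigLens))
    sigImgs <- list()
    for (L in uls) {
      s <- new("RayleighSignalSpec", signalLength = as.integer(L),
               blurSigma = sig@blurSigma, amplitude = sig@amplitude,
               orientation = sig@orientation)
      sigImgs[[as.character(L)]] <- list(
        H0 = makeRayleighSignal(s, "H0", n)@pixels,
        H1 = makeRayleighSignal(s, "H1", n)@pixels)
    }
  } else {
    mcspec <- specs$mc %||% mcClusterSpec()
  }

  objects <- array(0, dim = c(n, n, N))
  withSeed(seedStream(seed, "clb"), {
    for (i in seq_len(N)) {
      objects[, , i] <- sampleCLB(clb)$image@pixels
    }
  })
  if (task == "rayleigh") {
    withSeed(seedStream(seed, "signal"), {
      for (i in seq_len(N)) {
        cls <- labs[i]
        L <- sigLens[((i - 1L) %% nPerClass) + 1L]
        objects[, , i] <- objects[, , i] + sigImgs[[as.character(L)]][[cls]]
      }
    })
  } else {
    withSeed(seedStream(seed, "mc"), {
      for (i in seq_len(N)) {
        if (labs[i] == "H1") {
          smap <- synthMCCluster(mcspec)
          angle <- runif(1, mcspec@rotationRange[1], mcspec@rotationRange[2])
          crop <- rotateCropCluster(smap, angle, n)
          cc <- runif(1, mcspec@contrastRange[1], mcspec@contrastRange[2])
          objects[, , i] <- insertMC(objects[, , i], crop, cc)@pixels
        }
      }
    })
  }

  hr <- array(0, dim = c(n, n, N))
  nl <- if (deg@downsampleFactor > 1 && !deg@upsampleBack) {
    array(0, dim = c(n %/% deg@downsampleFactor,
                     n %/% deg@downsampleFactor, N))
  } else {
    array(0, dim = c(n, n, N))
  }
  lr <- nl
  degraded <- nl  # noiseless degraded objects
  withSeed(seedStream(seed, "noise"), {
    for (i in seq_len(N)) {
      f <- objects[, , i]
      hr[, , i] <- f + .draw_noise(n * n, noi)
      g <- gaussianBlur(f, deg@blurSigma)
      if (deg@downsampleFactor > 1) {
        g <- resampleImage(g, deg@downsampleFactor, "down")
      }
      gn <- g + .draw_noise(length(g), noi)
      if (deg@downsampleFactor > 1 && deg@upsampleBack) {
        g2 <- resampleImage(g, deg@downsampleFactor, "up")
        gn <- resampleImage(gn, deg@downsampleFactor, "up")
      } else {
        g2 <- g
      }
      lr[, , i] <- gn
      degraded[, , i] <- g2
    }
  })

  perm <- withSeed(seedStream(seed, "shuffle"), sample.int(N))
  gs <- list(task = task, clb = clb, degradation = deg, noise = noi,
             seed = seed, permutation = perm)
  if (task == "rayleigh") {
    gs$signal <- specs$signal %||% rayleighSignalSpec()
    gs$signalLengths <- sigLens
  } else {
    gs$mc <- mcspec
  }
  if (keepNoiseless) {
    gs$noiselessHR <- objects[, , perm, drop = FALSE]
    gs$noiselessLR <- degraded[, , perm, drop = FALSE]
  }
  labsf <- factor(labs[perm], levels = c("H0", "H1"))
  list(
    hr = new("ImagingEnsemble", images = hr[, , perm, drop = FALSE],
             labels = labsf, resolutionClass = "HR", generationSpec = gs),
    lr = new("ImagingEnsemble", images = lr[, , perm, drop = FALSE],
             labels = labsf, resolutionClass = "LR", generationSpec = gs)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ensemble mean squared error between two aligned ensembles
#'
#' Grand mean over all pixels and images of squared differences.
#'
#' @param ref,test aligned \code{\link{ImagingEnsemble}}s or (H, W, N)
#'   arrays of identical shape.
#' @return a scalar.
#' @export
ensembleMSE <- function(ref, test) {
  a <- if (is(ref, "ImagingEnsemble")) ref@images else ref
  b <- if (is(test, "ImagingEnsemble")) test@images else test
  if (!all(dim(a) == dim(b))) stop("ensemble shapes differ")
  mean((a - b)^2)
}
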