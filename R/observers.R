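## Hotelling-family linear observers: class statistics, truncated
## pseudoinversion, Gabor channels, templates and scoring.

.as_image_array <- function(x) {
  if (is(x, "ImagingEnsemble")) return(x@images)
  if (is.array(x) && length(dim(x)) == 3) return(x)
  stop("expected an ImagingEnsemble or a (H, W, N) array")
}

#' Fit class-conditional means and covariances
#'
#' Computes empirical class means, per-class covariances (1/(n-1)
#' normalization) and the pooled covariance K = (K0 + K1)/2 on the
#' (optionally centrally cropped) vectorized images.  The pooled covariance
#' is symmetrized by averaging with its transpose.  Its SVD is computed
#' lazily by \code{\link{ensureSVD}}.
#'
#' @param ensH0,ensH1 \code{\link{ImagingEnsemble}}s or (H, W, N) arrays
#'   holding the images of each class.
#' @param crop central crop side in pixels, or NULL for none.
#' @return a \code{\link{CovarianceModel}}.
#' @export
fitCovarianceModel <- function(ensH0, ensH1, crop = NULL) {
  X0 <- .crop_and_flatten(.as_image_array(ensH0), crop)
  X1 <- .crop_and_flatten(.as_image_array(ensH1), crop)
  if (nrow(X0) < 2 || nrow(X1) < 2) {
    stop("at least 2 images per class are required")
  }
  if (ncol(X0) != ncol(X1)) stop("class image shapes differ")
  m0 <- colMeans(X0)
  m1 <- colMeans(X1)
  K0 <- crossprod(sweep(X0, 2, m0)) / (nrow(X0) - 1)
  K1 <- crossprod(sweep(X1, 2, m1)) / (nrow(X1) - 1)
  K <- (K0 + K1) / 2
  K <- (K + t(K)) / 2
  new("CovarianceModel", meanH0 = m0, meanH1 = m1, covH0 = K0, covH1 = K1,
      pooledCov = K, svd = list(),
      nPerClass = c(nrow(X0), nrow(X1)),
      crop = if (is.null(crop)) NA_integer_ else as.integer(crop))
}

#' Difference of class means
#'
#' @param model a \code{\link{CovarianceModel}}.
#' @return the vector mean(H1) - mean(H0).
#' @export
deltaMean <- function(model) model@meanH1 - model@meanH0

#' Ensure the SVD of the pooled covariance is available
#'
#' @param model a \code{\link{CovarianceModel}}.
#' @return the model, with \code{model@svd} holding \code{d}, \code{u},
#'   \code{v}.
#' @export
ensureSVD <- function(model) {
  if (length(model@svd)) return(model)
  s <- svd(model@pooledCov)
  model@svd <- list(d = s$d, u = s$u, v = s$v)
  model
}

#' Truncated pseudoinverse of the pooled covariance
#'
#' \eqn{K_\lambda^+ = \sum_{i \le P} \sigma_i^{-1} u_i v_i^\top} with P the
#' largest index satisfying \eqn{\sigma_P \ge \lambda \sigma_1}; P = 0
#' yields the zero matrix.  Modes with singular values below machine
#' precision relative to \eqn{\sigma_1} are always dropped.
#'
#' @param model a \code{\link{CovarianceModel}} (SVD computed on demand).
#' @param lam truncation threshold in [0, 1].
#' @return the pseudoinverse matrix.
#' @export
truncatedPinv <- function(model, lam) {
  if (!is.numeric(lam) || lam < 0 || lam > 1) {
    stop("lam must lie in [0, 1]")
  }
  model <- ensureSVD(model)
  d <- model@svd$d
  eps <- max(d[1], 0) * 1e-12
  keep <- d >= max(lam * d[1], eps)
  P <- sum(keep)
  if (P == 0) {
    return(matrix(0, length(model@meanH0), length(model@meanH0)))
  }
  u <- model@svd$u[, seq_len(P), drop = FALSE]
  v <- model@svd$v[, seq_len(P), drop = FALSE]
  # K = sum sigma_i u_i v_i^T  =>  K+ = sum sigma_i^{-1} v_i u_i^T
  v %*% (t(u) / d[seq_len(P)])
}

.retained_modes <- function(model, lam) {
  d <- model@svd$d
  eps <- max(d[1], 0) * 1e-12
  sum(d >= max(lam * d[1], eps))
}

#' Regularized Hotelling observer template
#'
#' \eqn{w_{RHO}(\lambda) = K_\lambda^+ \Delta\bar f}.  With \eqn{\lambda
#' \to 0} on a well-conditioned covariance this reduces to the Hotelling
#' template \eqn{K^{-1} \Delta\bar f}.
#'
#' @param model a \code{\link{CovarianceModel}}.
#' @param lam truncation threshold in [0, 1].
#' @return a \code{\link{LinearTemplate}} of kind "RHO".
#' @export
rhoTemplate <- function(model, lam) {
  Kp <- truncatedPinv(model, lam)
  model <- ensureSVD(model)
  w <- as.numeric(Kp %*% deltaMean(model))
  new("LinearTemplate", weights = w, kind = "RHO", lambda = lam,
      retainedModes = as.integer(.retained_modes(model, lam)),
      channels = NULL, crop = model@crop)
}

#' Hotelling observer template
#'
#' Direct solve \eqn{w_{HO} = K^{-1} \Delta\bar f}; requires an invertible
#' pooled covariance.
#'
#' @param model a \code{\link{CovarianceModel}}.
#' @return a \code{\link{LinearTemplate}} of kind "HO".
#' @export
hoTemplate <- function(model) {
  w <- as.numeric(solve(model@pooledCov, deltaMean(model)))
  new("LinearTemplate", weights = w, kind = "HO", crop = model@crop)
}

#' Construct a Gabor channel-bank specification
#'
#' Default bank: six 1-octave passbands with centre frequencies 3/256,
#' 3/128, 3/64, 3/32, 3/16 and 3/8 cycles/pixel, five orientations
#' (0, 2pi/5, 4pi/5, 6pi/5, 8pi/5) and two phases (0, pi/2) - 60 channels.
#' Channel widths follow the 1-octave convention
#' \eqn{w_i = 6 \ln 2 / (\pi \nu_i)}.
#'
#' @param gridSize image side the channels will be discretized on.
#' @param centerFrequencies cycles/pixel, below 0.5.
#' @param orientations radians.
#' @param phases radians.
#' @return a \code{\link{GaborChannelSpec}}.
#' @export
gaborChannelSpec <- function(gridSize = 64L,
                             centerFrequencies = 3 / c(256, 128, 64, 32, 16, 8),
                             orientations = 2 * pi * (0:4) / 5,
                             phases = c(0, pi / 2)) {
  new("GaborChannelSpec",
      centerFrequencies = centerFrequencies, orientations = orientations,
      phases = phases, widths = 6 * log(2) / (pi * centerFrequencies),
      gridSize = as.integer(gridSize))
}

#' Discretize a Gabor channel bank into a channel matrix
#'
#' Row order: frequency-major, then orientation, then phase.  Coordinates
#' are centred on the grid ((x, y) = (0, 0) at the grid centre).
#'
#' @param spec a \code{\link{GaborChannelSpec}}.
#' @return a \code{\link{ChannelMatrix}} with one channel per row.
#' @examples
#' T <- buildGaborMatrix(gaborChannelSpec(32L))
#' nrow(channelMatrix(T))  # 60
#' @export
buildGaborMatrix <- function(spec) {
  validObject(spec)
  n <- spec@gridSize
  cc <- (n + 1) / 2
  x <- matrix(rep(seq_len(n) - cc, each = n), n, n)   # column coordinate
  y <- matrix(rep(seq_len(n) - cc, times = n), n, n)  # row coordinate
  r2 <- x^2 + y^2
  q <- length(spec@centerFrequencies) * length(spec@orientations) *
    length(spec@phases)
  M <- matrix(0, q, n * n)
  row <- 1L
  for (fi in seq_along(spec@centerFrequencies)) {
    nu <- spec@centerFrequencies[fi]
    w <- spec@widths[fi]
    env <- exp(-4 * log(2) * r2 / w^2)
    for (th in spec@orientations) {
      carrier <- 2 * pi * nu * (x * cos(th) + y * sin(th))
      for (ph in spec@phases) {
        M[row, ] <- as.numeric(env * cos(carrier + ph))
        row <- row + 1L
      }
    }
  }
  new("ChannelMatrix", mat = M, spec = spec)
}

#' Channelized Hotelling observer template
#'
#' Projects the images through the channel matrix (v = T f), fits the
#' channel-space class statistics and returns
#' \eqn{w_{CHO} = K_v^{-1} \Delta\bar v}.
#'
#' @param channels a \code{\link{ChannelMatrix}}.
#' @param ensH0,ensH1 per-class \code{\link{ImagingEnsemble}}s or arrays.
#' @param crop central crop applied before channelization (must match the
#'   channel grid size), or NULL.
#' @param ridge relative Tikhonov ridge added to the channel covariance
#'   (\code{ridge * mean(diag(Kv))}).  The default 0 solves the plain
#'   system and errors when the channelized covariance is numerically
#'   singular; a tiny ridge (e.g. 1e-8) stabilizes evaluation of strongly
#'   smoothed (super-resolved) images whose channel covariance is
#'   rank-deficient at reduced sample sizes.
#' @return a \code{\link{LinearTemplate}} of kind "CHO" with channel-space
#'   weights.
#' @export
choTemplate <- function(channels, ensH0, ensH1, crop = NULL, ridge = 0) {
  Tm <- channels@mat
  X0 <- .crop_and_flatten(.as_image_array(ensH0), crop)
  X1 <- .crop_and_flatten(.as_image_array(ensH1), crop)
  if (ncol(X0) != ncol(Tm)) {
    stop("channel matrix and (cropped) image dimension disagree")
  }
  V0 <- X0 %*% t(Tm)
  V1 <- X1 %*% t(Tm)
  m0 <- colMeans(V0)
  m1 <- colMeans(V1)
  K0 <- crossprod(sweep(V0, 2, m0)) / (nrow(V0) - 1)
  K1 <- crossprod(sweep(V1, 2, m1)) / (nrow(V1) - 1)
  Kv <- (K0 + K1) / 2
  if (ridge > 0) Kv <- Kv + ridge * mean(diag(Kv)) * diag(nrow(Kv))
  w <- tryCatch(solve(Kv, m1 - m0), error = function(e) {
    stop("channelized covariance is singular; use more samples per class")
  })
  new("LinearTemplate", weights = as.numeric(w), kind = "CHO",
      channels = channels,
      crop = if (is.null(crop)) NA_integer_ else as.integer(crop))
}

#' Apply a linear template to an ensemble
#'
#' Computes the test statistic t = w' f (or w' T f for channelized
#' templates) for every image, honouring the template's stored crop.
#'
#' @param template a \code{\link{LinearTemplate}}.
#' @param ens an \code{\link{ImagingEnsemble}}.
#' @param observerId label stored in the returned score set (defaults to
#'   the template kind).
#' @return a \code{\link{ScoreSet}} split by the ensemble labels.
#' @export
applyLinear <- function(template, ens, observerId = NULL) {
  if (!is(ens, "ImagingEnsemble")) stop("ens must be an ImagingEnsemble")
  X <- .crop_and_flatten(ens@images,
                         if (is.na(template@crop)) NULL else template@crop)
  if (template@kind == "CHO") {
    X <- X %*% t(template@channels@mat)
  }
  if (ncol(X) != length(template@weights)) {
    stop("template dimension does not match the (cropped) images")
  }
  t_all <- as.numeric(X %*% template@weights)
  labs <- ens@labels
  new("ScoreSet", scoresH0 = t_all[labs == "H0"],
      scoresH1 = t_all[labs == "H1"],
      observerId = observerId %||% template@kind)
}

#' Select the RHO truncation threshold on validation data
#'
#' Evaluates the RHO AUC on validation ensembles for every lambda in the
#' grid (default: the decade grid 1e-9 ... 1e-4) and returns the argmax;
#' ties are broken toward the larger lambda (more regularization).
#'
#' @param model a \code{\link{CovarianceModel}} fitted on training data.
#' @param valH0,valH1 validation \code{\link{ImagingEnsemble}}s or arrays
#'   for each class.
#' @param grid lambda grid.
#' @return list with \code{lambda} (selected value), \code{auc} (its
#'   validation AUC) and \code{table} (per-lambda data.frame).
#' @export
selectLambda <- function(model, valH0, valH1, grid = 10^seq(-9, -4)) {
  if (length(grid) == 0) stop("lambda grid must be non-empty")
  X0 <- .crop_and_flatten(.as_image_array(valH0),
                          if (is.na(model@crop)) NULL else model@crop)
  X1 <- .crop_and_flatten(.as_image_array(valH1),
                          if (is.na(model@crop)) NULL else model@crop)
  if (nrow(X0) == 0 || nrow(X1) == 0) {
    stop("validation ensembles must be non-empty")
  }
  model <- ensureSVD(model)
  grid <- sort(grid)
  aucs <- numeric(length(grid))
  modes <- integer(length(grid))
  for (i in seq_along(grid)) {
    tpl <- rhoTemplate(model, grid[i])
    s0 <- as.numeric(X0 %*% tpl@weights)
    s1 <- as.numeric(X1 %*% tpl@weights)
    aucs[i] <- empiricalAUC(new("ScoreSet", scoresH0 = s0, scoresH1 = s1))
    modes[i] <- tpl@retainedModes
  }
  best <- max(which(aucs == max(aucs)))  # ties toward larger lambda
  list(lambda = grid[best], auc = aucs[best],
       table = data.frame(lambda = grid, auc = aucs,
                          retainedModes = modes))
}
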