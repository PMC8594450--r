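## Phantom generation: clustered lumpy backgrounds, Rayleigh signals and
## synthetic microcalcification-cluster maps.

#' Construct CLB parameters
#'
#' Defaults are the standard mammographic-texture parameter set
#' (150 clusters of mean 20 blobs, ellipse half-axes 5 x 2 px, alpha = 2.1,
#' beta = 0.5, cluster spread 12 px) on a 128 x 128 field.
#'
#' @param meanClusters,meanBlobs Poisson means for cluster and per-cluster
#'   blob counts.
#' @param halfAxisX,halfAxisY blob ellipse half-axes, pixels.
#' @param alpha,beta blob decay coefficient and exponent.
#' @param clusterSpread Gaussian std of blob scatter, pixels.
#' @param fieldSize field side, pixels.
#' @param amplitude global intensity scale.
#' @return a \code{\link{CLBParams}} object.
#' @examples
#' p <- clbParams()
#' p
#' @export
clbParams <- function(meanClusters = 150, meanBlobs = 20, halfAxisX = 5,
                      halfAxisY = 2, alpha = 2.1, beta = 0.5,
                      clusterSpread = 12, fieldSize = 128L, amplitude = 1) {
  new("CLBParams",
      meanClusters = meanClusters, meanBlobs = meanBlobs,
      halfAxisX = halfAxisX, halfAxisY = halfAxisY, alpha = alpha,
      beta = beta, clusterSpread = clusterSpread,
      fieldSize = as.integer(fieldSize), amplitude = amplitude)
}

setMethod("show", "CLBParams", function(object) {
  cat(sprintf(
    "CLBParams: Kbar=%g Nbar=%g Lx=%g Ly=%g alpha=%g beta=%g sigma=%g field=%d amp=%g\n",
    object@meanClusters, object@meanBlobs, object@halfAxisX,
    object@halfAxisY, object@alpha, object@beta, object@clusterSpread,
    object@fieldSize, object@amplitude))
})

## margin by which cluster-centre sampling extends beyond the field, so
## that border pixels see the same blob flux as interior pixels
.clb_margin <- function(params) {
  3 * params@clusterSpread + 3 * max(params@halfAxisX, params@halfAxisY)
}

#' Sample one clustered lumpy background
#'
#' Draws K ~ Poisson(Kbar) cluster centres uniformly over the field extended
#' by a margin of 3*sigma + 3*max(Lx, Ly) per side, then Nk ~ Poisson(Nbar)
#' blobs per cluster with Gaussian(sigma) offsets and uniform orientations,
#' and renders the sum of elongated exponential blobs
#' \eqn{l(r, R_\theta) = \exp(-\alpha \|R_\theta r\|^\beta / L(R_\theta r))}
#' over the field (contributions falling outside the field are truncated).
#'
#' @param params a \code{\link{CLBParams}} object.
#' @param seed optional integer seed (local to this call).
#' @param realization optionally, a \code{\link{ClusterRealization}} to
#'   render instead of sampling a new one (used for reproduction and for
#'   forcing degenerate configurations in tests).
#' @param exact force exact per-pixel blob evaluation instead of the default
#'   hybrid near/far evaluation (slower; used for validation).
#' @return a list with elements \code{image} (an \code{\link{ObjectImage}}
#'   with role "background") and \code{realization} (a
#'   \code{\link{ClusterRealization}}).
#' @examples
#' r <- sampleCLB(clbParams(fieldSize = 64L, meanClusters = 40), seed = 1)
#' dim(pixels(r$image))
#' @export
sampleCLB <- function(params, seed = NULL, realization = NULL,
                      exact = FALSE) {
  validObject(params)
  n <- params@fieldSize
  if (is.null(realization)) {
    realization <- withSeed(seed, {
      margin <- .clb_margin(params)
      K <- rpois(1, params@meanClusters)
      centers <- cbind(runif(K, -margin, n - 1 + margin),
                       runif(K, -margin, n - 1 + margin))
      Nk <- if (K > 0) rpois(K, params@meanBlobs) else integer(0)
      nb <- sum(Nk)
      offsets <- cbind(rnorm(nb, 0, params@clusterSpread),
                       rnorm(nb, 0, params@clusterSpread))
      angles <- runif(nb, 0, 2 * pi)
      new("ClusterRealization", nClusters = as.integer(K),
          clusterCenters = centers, blobsPerCluster = as.integer(Nk),
          blobOffsets = offsets, blobAngles = angles)
    })
  }
  validObject(realization)
  ctr <- realization@clusterCenters[
    rep(seq_len(realization@nClusters), realization@blobsPerCluster), ,
    drop = FALSE]
  bx <- ctr[, 1] + realization@blobOffsets[, 1]
  by <- ctr[, 2] + realization@blobOffsets[, 2]
  px <- .clb_render(n, bx, by, realization@blobAngles, params@alpha,
                    params@beta, params@halfAxisX, params@halfAxisY,
                    params@amplitude, exact)
  img <- new("ObjectImage", pixels = px, role = "background",
             hypothesis = "none",
             provenance = list(seed = seed, clb = params,
                               nBlobs = length(bx)))
  list(image = img, realization = realization)
}

#' Construct a Rayleigh signal specification
#'
#' @param signalLength signal length L, pixels (typically 5..9).
#' @param blurSigma signal formation blur, pixels (default 1.375).
#' @param amplitude impulse/line height before blur.  The default is the
#'   package's calibrated value for the Rayleigh study configuration.
#' @return a \code{\link{RayleighSignalSpec}}.
#' @export
rayleighSignalSpec <- function(signalLength = 7L, blurSigma = 1.375,
                               amplitude = 10) {
  new("RayleighSignalSpec", signalLength = as.integer(signalLength),
      blurSigma = blurSigma, amplitude = amplitude,
      orientation = "horizontal")
}

#' Make a Rayleigh discrimination signal image
#'
#' Under H0 the signal consists of two impulses of height \code{amplitude}
#' separated by L - 2 pixels on the central row; under H1 it is a horizontal
#' line of length L.  Both are convolved with a Gaussian of standard
#' deviation \code{blurSigma} and placed so the signal centroid falls on the
#' image centre (to the nearest half pixel, since impulses sit on the pixel
#' grid).
#'
#' @param spec a \code{\link{RayleighSignalSpec}}.
#' @param hypothesis "H0" (two points) or "H1" (line).
#' @param gridSize image side, pixels; must be at least 2 L.
#' @return an \code{\link{ObjectImage}} with role "signal".
#' @examples
#' s <- makeRayleighSignal(rayleighSignalSpec(8L), "H0", 64L)
#' @export
makeRayleighSignal <- function(spec, hypothesis, gridSize) {
  validObject(spec)
  if (!hypothesis %in% c("H0", "H1")) {
    stop("hypothesis must be 'H0' or 'H1'")
  }
  n <- as.integer(gridSize)
  if (length(spec@signalLength) != 1) {
    stop("makeRayleighSignal needs a single signal length")
  }
  L <- spec@signalLength
  if (n < 2 * L) stop("gridSize must be at least 2 * signalLength")
  c0 <- (n + 1) / 2                       # geometric centre, 1-based
  yc <- floor(c0 + 0.5)                   # central row
  base <- matrix(0, n, n)
  if (hypothesis == "H0") {
    s <- L - 2                            # impulse separation
    x1 <- floor(c0 - s / 2 + 0.5)
    base[yc, c(x1, x1 + s)] <- spec@amplitude
  } else {
    x1 <- floor(c0 - (L - 1) / 2 + 0.5)
    base[yc, x1:(x1 + L - 1)] <- spec@amplitude
  }
  px <- .gauss_filter(base, spec@blurSigma, -1L)
  nz <- which(px > max(px) * 1e-12, arr.ind = TRUE)
  bbox <- c(min(nz[, 1]), max(nz[, 1]), min(nz[, 2]), max(nz[, 2]))
  new("ObjectImage", pixels = px, role = "signal", hypothesis = hypothesis,
      provenance = list(spec = spec, bbox = bbox))
}

#' Construct a synthetic MC-cluster map specification
#'
#' @param canvasSize canvas side, pixels.
#' @param nMCsRange integer interval for the number of microcalcifications.
#' @param clusterRadius radius containing the MC centres, pixels.
#' @param mcSizeRange interval of MC radii, pixels.
#' @param contrastRange interval for the insertion contrast factor.
#' @param rotationRange rotation interval, degrees.
#' @return an \code{\link{MCClusterSpec}}.
#' @export
mcClusterSpec <- function(canvasSize = 200L, nMCsRange = c(8L, 16L),
                          clusterRadius = 25, mcSizeRange = c(1.5, 4),
                          contrastRange = c(0.05, 0.06),
                          rotationRange = c(0, 360)) {
  new("MCClusterSpec", canvasSize = as.integer(canvasSize),
      nMCsRange = as.integer(nMCsRange), clusterRadius = clusterRadius,
      mcSizeRange = mcSizeRange, contrastRange = contrastRange,
      rotationRange = rotationRange)
}

#' Synthesize a microcalcification-cluster map
#'
#' Generates a sparse cluster of small bright irregular blobs on a square
#' canvas, values in [0, 1] on an exactly-zero background: a cluster
#' centroid is drawn near the canvas centre, MC centres are scattered
#' uniformly within \code{clusterRadius} of it, and each MC is a radially
#' decaying blob whose support radius is modulated irregularly with angle
#' (shrink-only, so a 1-px MC occupies exactly one pixel).
#'
#' @param spec an \code{\link{MCClusterSpec}}.
#' @param seed optional integer seed (local to this call).
#' @return an \code{\link{ObjectImage}} with role "signal" (the raw map,
#'   before rotation/cropping/insertion).
#' @export
synthMCCluster <- function(spec, seed = NULL) {
  validObject(spec)
  n <- spec@canvasSize
  withSeed(seed, {
    px <- matrix(0, n, n)
    c0 <- (n + 1) / 2
    # centroid near the canvas centre so the cluster survives rotation and
    # cropping (spread scales with the cluster radius)
    maxd <- max(4, min(spec@clusterRadius, n / 2 - spec@clusterRadius - 4))
    ang <- runif(1, 0, 2 * pi)
    rad <- maxd * sqrt(runif(1))
    cx <- c0 + rad * cos(ang)
    cy <- c0 + rad * sin(ang)
    nmc <- if (spec@nMCsRange[1] == spec@nMCsRange[2]) spec@nMCsRange[1] else
      sample(spec@nMCsRange[1]:spec@nMCsRange[2], 1)
    for (i in seq_len(nmc)) {
      a <- runif(1, 0, 2 * pi)
      r <- spec@clusterRadius * sqrt(runif(1))
      mx <- cx + r * cos(a)
      my <- cy + r * sin(a)
      s <- runif(1, spec@mcSizeRange[1], spec@mcSizeRange[2])
      psi1 <- runif(1, 0, 2 * pi)
      psi2 <- runif(1, 0, 2 * pi)
      bright <- runif(1, 0.7, 1)
      xi <- round(mx); yi <- round(my)
      if (s <= 1) {
        # single-pixel microcalcification: exactly the nearest pixel
        if (xi >= 1 && xi <= n && yi >= 1 && yi <= n) {
          px[yi, xi] <- max(px[yi, xi], bright)
        }
        next
      }
      x0 <- max(1, floor(mx - s - 1)); x1 <- min(n, ceiling(mx + s + 1))
      y0 <- max(1, floor(my - s - 1)); y1 <- min(n, ceiling(my + s + 1))
      for (x in x0:x1) {
        for (y in y0:y1) {
          dx <- x - mx; dy <- y - my
          d <- sqrt(dx^2 + dy^2)
          phi <- atan2(dy, dx)
          # shrink-only angular modulation of the support radius
          u <- 0.6 * (1 + sin(2 * phi + psi1)) / 2 +
               0.4 * (1 + sin(3 * phi + psi2)) / 2
          seff <- s * (0.6 + 0.4 * u)
          if (d < seff) {
            v <- bright * (1 - (d / seff)^2)
            px[y, x] <- min(1, max(px[y, x], v))
          }
        }
      }
      # the MC centre pixel is always lit
      if (xi >= 1 && xi <= n && yi >= 1 && yi <= n) {
        px[yi, xi] <- max(px[yi, xi], bright)
      }
    }
    new("ObjectImage", pixels = px, role = "signal", hypothesis = "none",
        provenance = list(spec = spec, seed = seed, nMCs = nmc))
  })
}

#' Rotate an MC-cluster map and crop to the insertion size
#'
#' Rotates counterclockwise about the canvas centre with bilinear
#' interpolation and zero fill, then centrally crops to \code{cropSize}.
#'
#' @param sMC an \code{\link{ObjectImage}} (or matrix) holding the MC map.
#' @param angle rotation angle, degrees counterclockwise.
#' @param cropSize output side, pixels (default 128).
#' @return an \code{\link{ObjectImage}} with role "signal".
#' @export
rotateCropCluster <- function(sMC, angle, cropSize = 128L) {
  px <- if (is(sMC, "ObjectImage")) sMC@pixels else sMC
  if (nrow(px) != ncol(px)) stop("MC map must be square")
  if (cropSize > nrow(px)) stop("cropSize exceeds the canvas")
  if (angle %% 360 != 0) {
    # EBImage rotates clockwise for positive angles in the raster
    # convention; negate for a counterclockwise rotation of the matrix.
    rot <- EBImage::rotate(EBImage::Image(px), -angle, bg.col = 0,
                           output.dim = dim(px))
    px <- EBImage::imageData(rot)
  }
  px[px < 0] <- 0
  px[px > 1] <- 1
  out <- centralCrop(px, cropSize)
  new("ObjectImage", pixels = out, role = "signal", hypothesis = "none",
      provenance = list(angle = angle))
}

#' Insert an MC-cluster map into a background multiplicatively
#'
#' Returns the signal-present composite \code{fb * (c * sMC + 1)}.
#'
#' @param fb background \code{\link{ObjectImage}} (or matrix).
#' @param sMCcrop cropped MC map \code{\link{ObjectImage}} (or matrix) of
#'   the same size.
#' @param contrast contrast factor c >= 0.
#' @return an \code{\link{ObjectImage}} with role "composite", hypothesis
#'   "H1".
#' @export
insertMC <- function(fb, sMCcrop, contrast) {
  if (contrast < 0) stop("contrast must be >= 0")
  fbp <- if (is(fb, "ObjectImage")) fb@pixels else fb
  sp <- if (is(sMCcrop, "ObjectImage")) sMCcrop@pixels else sMCcrop
  if (!all(dim(fbp) == dim(sp))) stop("background and MC map shapes differ")
  new("ObjectImage", pixels = fbp * (contrast * sp + 1), role = "composite",
      hypothesis = "H1", provenance = list(contrast = contrast))
}
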