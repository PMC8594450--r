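## S4 classes for the simulation / observer pipeline.

#' Parameters of the clustered lumpy background model
#'
#' Holds the CLB texture parameters: the mean number of clusters per field,
#' the mean number of blobs per cluster, the blob ellipse half-axes, the
#' blob decay parameters and the Gaussian scatter of blobs about their
#' cluster centre.  Defaults are the standard mammographic-texture values
#' for a 128x128 field.
#'
#' @slot meanClusters mean cluster count per field (Poisson mean).
#' @slot meanBlobs mean blobs per cluster (Poisson mean).
#' @slot halfAxisX,halfAxisY blob ellipse half-axes, pixels.
#' @slot alpha,beta blob decay coefficient and exponent (dimensionless).
#' @slot clusterSpread Gaussian std of blob scatter about the cluster
#'   centre, pixels.
#' @slot fieldSize field side length, pixels.
#' @slot amplitude global multiplicative intensity scale.
#' @exportClass CLBParams
setClass("CLBParams",
  representation(
    meanClusters = "numeric", meanBlobs = "numeric",
    halfAxisX = "numeric", halfAxisY = "numeric",
    alpha = "numeric", beta = "numeric",
    clusterSpread = "numeric", fieldSize = "integer",
    amplitude = "numeric"
  )
)

setValidity("CLBParams", function(object) {
  vals <- c(
    meanClusters = object@meanClusters, meanBlobs = object@meanBlobs,
    halfAxisX = object@halfAxisX, halfAxisY = object@halfAxisY,
    alpha = object@alpha, beta = object@beta,
    clusterSpread = object@clusterSpread,
    fieldSize = as.numeric(object@fieldSize), amplitude = object@amplitude
  )
  if (any(!is.finite(vals))) {
    return("all CLB parameters must be finite")
  }
  bad <- names(vals)[vals <= 0]
  if (length(bad) > 0) {
    return(paste0("CLB parameters must be strictly positive: ",
                  paste(bad, collapse = ", ")))
  }
  TRUE
})

#' One sampled realization of the CLB cluster/blob process
#'
#' @slot nClusters realized cluster count K.
#' @slot clusterCenters K x 2 matrix of cluster centres (x, y), pixels.
#' @slot blobsPerCluster integer vector of blob counts per cluster.
#' @slot blobOffsets sum(Nk) x 2 matrix of blob offsets from their cluster
#'   centre, grouped by cluster.
#' @slot blobAngles blob orientation angles in [0, 2*pi).
#' @exportClass ClusterRealization
setClass("ClusterRealization",
  representation(
    nClusters = "integer", clusterCenters = "matrix",
    blobsPerCluster = "integer", blobOffsets = "matrix",
    blobAngles = "numeric"
  )
)

setValidity("ClusterRealization", function(object) {
  K <- object@nClusters
  if (K < 0) return("nClusters must be >= 0")
  if (nrow(object@clusterCenters) != K) {
    return("clusterCenters must have one row per cluster")
  }
  if (length(object@blobsPerCluster) != K) {
    return("blobsPerCluster must have one entry per cluster")
  }
  nb <- sum(object@blobsPerCluster)
  if (nrow(object@blobOffsets) != nb || length(object@blobAngles) != nb) {
    return("blobOffsets / blobAngles must have one row per blob")
  }
  if (nb > 0 && (any(object@blobAngles < 0) ||
                 any(object@blobAngles >= 2 * pi))) {
    return("blobAngles must lie in [0, 2*pi)")
  }
  TRUE
})

#' A single 2-D object image with role and hypothesis tags
#'
#' @slot pixels square numeric matrix of pixel values.
#' @slot role one of "background", "signal", "composite".
#' @slot hypothesis one of "H0", "H1", "none".
#' @slot provenance list of seeds/specs that generated the image.
#' @exportClass ObjectImage
setClass("ObjectImage",
  representation(
    pixels = "matrix", role = "character", hypothesis = "character",
    provenance = "list"
  ),
  prototype(role = "background", hypothesis = "none", provenance = list())
)

setValidity("ObjectImage", function(object) {
  if (!all(is.finite(object@pixels))) return("pixels must be finite")
  if (nrow(object@pixels) != ncol(object@pixels)) {
    return("pixels must be a square grid")
  }
  if (!object@role %in% c("background", "signal", "composite")) {
    return("role must be background, signal or composite")
  }
  if (!object@hypothesis %in% c("H0", "H1", "none")) {
    return("hypothesis must be H0, H1 or none")
  }
  TRUE
})

#' Specification of the Rayleigh discrimination signal
#'
#' Under H0 the signal is two impulses of height \code{amplitude} separated
#' by \code{signalLength - 2} pixels; under H1 it is a horizontal line of
#' length \code{signalLength}.  Both are convolved with a Gaussian of
#' standard deviation \code{blurSigma} and centred on the image.
#'
#' @slot signalLength signal length L, pixels (integer, >= 3).
#' @slot blurSigma signal formation blur, pixels.
#' @slot amplitude impulse/line height before blur.
#' @slot orientation fixed "horizontal".
#' @exportClass RayleighSignalSpec
setClass("RayleighSignalSpec",
  representation(
    signalLength = "integer", blurSigma = "numeric",
    amplitude = "numeric", orientation = "character"
  ),
  prototype(blurSigma = 1.375, orientation = "horizontal")
)

setValidity("RayleighSignalSpec", function(object) {
  # signalLength may be a vector (a mixture of lengths for ensemble drivers)
  if (length(object@signalLength) < 1 || any(object@signalLength < 3)) {
    return("signalLength must be >= 3")
  }
  if (object@blurSigma <= 0) return("blurSigma must be > 0")
  if (object@amplitude <= 0) return("amplitude must be > 0")
  if (object@orientation != "horizontal") {
    return("only horizontal orientation is supported")
  }
  TRUE
})

#' Specification of a synthetic microcalcification-cluster map
#'
#' Describes a sparse cluster of small bright irregular blobs on a square
#' canvas with values in [0, 1]; the map is rotated and cropped before
#' multiplicative insertion into a background.
#'
#' @slot canvasSize canvas side, pixels (default 200).
#' @slot nMCsRange integer interval for the number of microcalcifications.
#' @slot clusterRadius radius containing the MC centres, pixels.
#' @slot mcSizeRange interval of MC radii, pixels.
#' @slot contrastRange interval for the insertion contrast factor c.
#' @slot rotationRange rotation interval, degrees.
#' @exportClass MCClusterSpec
setClass("MCClusterSpec",
  representation(
    canvasSize = "integer", nMCsRange = "integer",
    clusterRadius = "numeric", mcSizeRange = "numeric",
    contrastRange = "numeric", rotationRange = "numeric"
  )
)

setValidity("MCClusterSpec", function(object) {
  if (object@canvasSize < 128) return("canvasSize must be >= 128")
  if (object@nMCsRange[1] < 1) return("nMCsRange lower bound must be >= 1")
  if (object@nMCsRange[2] < object@nMCsRange[1]) {
    return("nMCsRange must be a non-empty interval")
  }
  if (object@clusterRadius <= 0 ||
      2 * object@clusterRadius > object@canvasSize) {
    return("clusterRadius must be positive and fit inside the canvas")
  }
  if (any(object@contrastRange <= 0) || any(object@contrastRange >= 1)) {
    return("contrastRange must lie within (0, 1)")
  }
  if (any(object@mcSizeRange <= 0)) return("mcSizeRange must be positive")
  TRUE
})

#' Degradation operator specification (blur / decimation / upsampling)
#'
#' @slot blurSigma Gaussian blur std, pixels.
#' @slot downsampleFactor integer decimation factor (1 = none).
#' @slot upsampleBack whether the LR image is bilinearly upsampled back to
#'   the HR grid after noise is added.
#' @slot task "rayleigh" or "mc".
#' @exportClass DegradationSpec
setClass("DegradationSpec",
  representation(
    blurSigma = "numeric", downsampleFactor = "integer",
    upsampleBack = "logical", task = "character"
  )
)

setValidity("DegradationSpec", function(object) {
  if (object@blurSigma <= 0) return("blurSigma must be > 0")
  if (object@downsampleFactor < 1) return("downsampleFactor must be >= 1")
  if (!object@task %in% c("rayleigh", "mc")) {
    return("task must be rayleigh or mc")
  }
  TRUE
})

#' Mixed Poisson-Gaussian measurement-noise specification
#'
#' Per pixel the noise is \eqn{\sigma_p (P - \lambda_0)/\sqrt{\lambda_0} +
#' \sigma_g Z} with \eqn{P \sim Poisson(\lambda_0)} and Z standard normal,
#' i.e. zero mean and standard deviation
#' \eqn{\sqrt{\sigma_p^2 + \sigma_g^2}} independent of the image.
#'
#' @slot poissonScale scaled-Poisson component std sigma_p.
#' @slot gaussianStd Gaussian component std sigma_g.
#' @slot poissonRate internal Poisson rate lambda_0.
#' @exportClass NoiseSpec
setClass("NoiseSpec",
  representation(
    poissonScale = "numeric", gaussianStd = "numeric", poissonRate = "numeric"
  ),
  prototype(poissonRate = 10)
)

setValidity("NoiseSpec", function(object) {
  if (object@poissonScale < 0) return("poissonScale must be >= 0")
  if (object@gaussianStd < 0) return("gaussianStd must be >= 0")
  if (object@poissonRate <= 0) return("poissonRate must be > 0")
  TRUE
})

#' A labeled stack of images of one resolution class
#'
#' @slot images numeric array (H, W, N).
#' @slot labels factor with levels H0/H1, one per image.
#' @slot resolutionClass "HR", "LR" or "SR".
#' @slot generationSpec list with the specs and seeds that generated the
#'   ensemble (and optionally the noiseless composites for semionline
#'   training).
#' @exportClass ImagingEnsemble
setClass("ImagingEnsemble",
  representation(
    images = "array", labels = "factor", resolutionClass = "character",
    generationSpec = "list"
  ),
  prototype(generationSpec = list())
)

setValidity("ImagingEnsemble", function(object) {
  d <- dim(object@images)
  if (length(d) != 3) return("images must be a 3-D array (H, W, N)")
  if (length(object@labels) != d[3]) {
    return("labels must have one entry per image")
  }
  if (!all(levels(object@labels) %in% c("H0", "H1"))) {
    return("labels must use levels H0/H1")
  }
  if (!object@resolutionClass %in% c("HR", "LR", "SR")) {
    return("resolutionClass must be HR, LR or SR")
  }
  TRUE
})

#' Class-conditional first/second-order statistics of an image ensemble
#'
#' @slot meanH0,meanH1 class-conditional mean vectors.
#' @slot covH0,covH1 class-conditional covariance matrices (1/(n-1)).
#' @slot pooledCov pooled covariance (K0 + K1)/2, symmetrized.
#' @slot svd list with d (singular values), u, v once computed (see
#'   \code{\link{ensureSVD}}); empty before that.
#' @slot nPerClass integer vector: samples per class.
#' @slot crop central crop size used (NA when none).
#' @exportClass CovarianceModel
setClass("CovarianceModel",
  representation(
    meanH0 = "numeric", meanH1 = "numeric",
    covH0 = "matrix", covH1 = "matrix", pooledCov = "matrix",
    svd = "list", nPerClass = "integer", crop = "integer"
  ),
  prototype(svd = list(), crop = NA_integer_)
)

setValidity("CovarianceModel", function(object) {
  d <- length(object@meanH0)
  if (length(object@meanH1) != d) return("class means must match in length")
  if (!all(dim(object@pooledCov) == c(d, d))) {
    return("pooledCov dimension must match the means")
  }
  asym <- max(abs(object@pooledCov - t(object@pooledCov)))
  scale <- max(abs(object@pooledCov), 1e-300)
  if (asym / scale > 1e-8) return("pooledCov must be symmetric")
  TRUE
})

#' Gabor channel bank specification
#'
#' Channel i is a sinusoid-modulated Gaussian
#' \eqn{C_i(x, y) = \exp(-4 \ln 2 (x^2+y^2)/w_i^2)
#'   \cos(2\pi\nu_i(x\cos\theta_i + y\sin\theta_i) + \phi_i)}.
#' Widths follow the 1-octave bandwidth convention
#' \eqn{w_i = 6 \ln 2 / (\pi \nu_i)}.
#'
#' @slot centerFrequencies cycles/pixel (must be < 0.5).
#' @slot orientations radians.
#' @slot phases radians.
#' @slot widths Gaussian envelope FWHM per frequency, pixels (derived).
#' @slot gridSize image side the channels are discretized on.
#' @exportClass GaborChannelSpec
setClass("GaborChannelSpec",
  representation(
    centerFrequencies = "numeric", orientations = "numeric",
    phases = "numeric", widths = "numeric", gridSize = "integer"
  )
)

setValidity("GaborChannelSpec", function(object) {
  if (any(object@centerFrequencies >= 0.5)) {
    return("center frequencies must be below 0.5 cycles/pixel (Nyquist)")
  }
  if (any(object@centerFrequencies <= 0)) {
    return("center frequencies must be positive")
  }
  if (length(object@widths) != length(object@centerFrequencies)) {
    return("one width per center frequency required")
  }
  if (any(object@widths <= 0)) return("widths must be positive")
  if (object@gridSize < 2) return("gridSize must be >= 2")
  TRUE
})

#' Discretized channel matrix
#'
#' @slot mat q x n matrix; one discretized channel per row.
#' @slot spec the \code{GaborChannelSpec} that produced it.
#' @exportClass ChannelMatrix
setClass("ChannelMatrix",
  representation(mat = "matrix", spec = "GaborChannelSpec")
)

#' A linear observer template
#'
#' @slot weights image-length (HO/RHO) or channel-length (CHO) weights.
#' @slot kind "HO", "RHO" or "CHO".
#' @slot lambda truncation threshold for RHO (NA otherwise).
#' @slot retainedModes number of singular modes retained (NA for HO/CHO).
#' @slot channels the \code{ChannelMatrix} for CHO templates (NULL else).
#' @slot crop central crop the template expects (NA when none).
#' @exportClass LinearTemplate
setClass("LinearTemplate",
  representation(
    weights = "numeric", kind = "character", lambda = "numeric",
    retainedModes = "integer", channels = "ANY", crop = "integer"
  ),
  prototype(lambda = NA_real_, retainedModes = NA_integer_,
            channels = NULL, crop = NA_integer_)
)

setValidity("LinearTemplate", function(object) {
  if (!all(is.finite(object@weights))) return("weights must be finite")
  if (!object@kind %in% c("HO", "RHO", "CHO")) {
    return("kind must be HO, RHO or CHO")
  }
  TRUE
})

#' Paired per-class test-statistic samples
#'
#' @slot scoresH0,scoresH1 test statistics under each hypothesis.
#' @slot observerId label of the observer that produced the scores.
#' @slot threshold optional operating point.
#' @exportClass ScoreSet
setClass("ScoreSet",
  representation(
    scoresH0 = "numeric", scoresH1 = "numeric", observerId = "character",
    threshold = "numeric"
  ),
  prototype(observerId = "observer", threshold = numeric(0))
)

setValidity("ScoreSet", function(object) {
  if (!all(is.finite(object@scoresH0)) || !all(is.finite(object@scoresH1))) {
    return("scores must be finite")
  }
  TRUE
})

#' Empirical AUC with a DeLong confidence interval
#'
#' @slot auc Mann-Whitney AUC estimate.
#' @slot ciLow,ciHigh two-sided normal-approximation CI, clipped to [0, 1].
#' @slot variance DeLong structural-components variance of the AUC.
#' @slot n0,n1 class sample sizes.
#' @slot level confidence level.
#' @slot degenerate TRUE when the variance collapsed (AUC exactly 0 or 1).
#' @exportClass ROCResult
setClass("ROCResult",
  representation(
    auc = "numeric", ciLow = "numeric", ciHigh = "numeric",
    variance = "numeric", n0 = "integer", n1 = "integer",
    level = "numeric", degenerate = "logical"
  ),
  prototype(level = 0.95, degenerate = FALSE)
)

setValidity("ROCResult", function(object) {
  if (object@auc < 0 || object@auc > 1) return("auc must lie in [0, 1]")
  if (object@ciLow > object@auc || object@ciHigh < object@auc) {
    return("CI must bracket the AUC")
  }
  TRUE
})

#' Traditional image-quality metrics for an ensemble pair
#'
#' @slot ensembleMSE grand mean of squared pixel differences.
#' @slot psnr peak signal-to-noise ratio, dB (Inf when MSE = 0).
#' @slot ssim mean per-image structural similarity.
#' @slot peak PSNR/SSIM dynamic-range reference.
#' @slot nImages number of image pairs compared.
#' @exportClass IQMetrics
setClass("IQMetrics",
  representation(
    ensembleMSE = "numeric", psnr = "numeric", ssim = "numeric",
    peak = "numeric", nImages = "integer"
  )
)

#' Result of an experiment sweep
#'
#' @slot axis swept axis ("signal_length", "n_layers", "n_blocks",
#'   "n_train").
#' @slot table tidy data.frame, one row per (level, resolution class,
#'   observer) cell.
#' @slot details list with per-level extras (spectra, histories, seeds).
#' @exportClass SweepResult
setClass("SweepResult",
  representation(axis = "character", table = "data.frame", details = "list"),
  prototype(details = list())
)

#' Handle for a small trainable convolutional model
#'
#' @slot kind "srcnn" or "resnet_observer".
#' @slot spec architecture specification list.
#' @slot params named list of weight arrays.
#' @slot trained whether the model has been trained.
#' @slot history per-epoch training log.
#' @slot provenance seeds, configs and data fingerprints.
#' @exportClass ConvNetModel
setClass("ConvNetModel",
  representation(
    kind = "character", spec = "list", params = "list", trained = "logical",
    history = "data.frame", provenance = "list"
  ),
  prototype(trained = FALSE, history = data.frame(), provenance = list())
)

#' Training configuration for the trainable components
#'
#' @slot nTrain,nVal training and validation sample counts.
#' @slot batchSize mini-batch size.
#' @slot learningRate Adam step size.
#' @slot maxEpochs epoch budget.
#' @slot optimizer "adam".
#' @slot seed RNG seed for shuffling/initial noise.
#' @slot semionlineNoise re-draw the measurement noise each epoch from the
#'   stored noiseless composites.
#' @slot flipAugment fourfold flip augmentation of the training images.
#' @slot earlySelection return the best-validation checkpoint.
#' @exportClass TrainingConfig
setClass("TrainingConfig",
  representation(
    nTrain = "integer", nVal = "integer", batchSize = "integer",
    learningRate = "numeric", maxEpochs = "integer", optimizer = "character",
    seed = "integer", semionlineNoise = "logical", flipAugment = "logical",
    earlySelection = "logical"
  ),
  prototype(optimizer = "adam", semionlineNoise = FALSE, flipAugment = FALSE,
            earlySelection = TRUE)
)

setValidity("TrainingConfig", function(object) {
  if (object@nTrain < 1 || object@batchSize < 1 || object@maxEpochs < 1) {
    return("counts must be positive")
  }
  if (object@learningRate <= 0) return("learningRate must be > 0")
  if (object@optimizer != "adam") return("only the adam optimizer is supported")
  TRUE
})
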