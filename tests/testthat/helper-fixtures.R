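# Shared miniature fixtures, built once per test run and cached.
# Small 64-px fields keep the CLB density per area equal to the default
# 128-px configuration (mean clusters scaled by area).

.fix_cache <- new.env(parent = emptyenv())

fix_get <- function(name, builder) {
  if (!exists(name, envir = .fix_cache)) {
    assign(name, builder(), envir = .fix_cache)
  }
  get(name, envir = .fix_cache)
}

clb64 <- function(amplitude = 2.802) {
  clbParams(meanClusters = 150 / 4, fieldSize = 64L, amplitude = amplitude)
}

# a single forced blob at the field centre, axis-aligned
single_blob_realization <- function(cx, cy, theta = 0) {
  new("ClusterRealization", nClusters = 1L,
      clusterCenters = matrix(c(cx, cy), 1, 2),
      blobsPerCluster = 1L, blobOffsets = matrix(0, 1, 2),
      blobAngles = theta)
}

# small paired rayleigh ensembles shared across observer/neural tests
fix_rayleigh_small <- function() {
  fix_get("rayleigh_small", function() {
    buildTaskEnsembles(
      "rayleigh", 120,
      specs = list(clb = clb64(),
                   signal = rayleighSignalSpec(7L, amplitude = 10)),
      seed = 101)
  })
}

# multivariate normal draws via a Cholesky factor
rmvn <- function(n, mu, K) {
  d <- length(mu)
  Z <- matrix(rnorm(n * d), n, d)
  sweep(Z %*% chol(K), 2, mu, `+`)
}

# score sets as (H,W,N)=(1x d) image stacks are awkward for toy cases;
# build an ImagingEnsemble from a (N, d) matrix of square images
ens_from_rows <- function(X, labels, rc = "HR") {
  side <- as.integer(sqrt(ncol(X)))
  stopifnot(side * side == ncol(X))
  arr <- array(t(X), dim = c(side, side, nrow(X)))
  new("ImagingEnsemble", images = arr,
      labels = factor(labels, levels = c("H0", "H1")),
      resolutionClass = rc, generationSpec = list())
}
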