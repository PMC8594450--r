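## Configuration, persistence, fixtures and export.

.default_config <- function(task = "rayleigh") {
  list(
    task = task,
    master_seed = 1L,
    clb = list(mean_clusters = 150, mean_blobs = 20, half_axis_x = 5,
               half_axis_y = 2, alpha = 2.1, beta = 0.5, cluster_spread = 12,
               field_size = 128L,
               amplitude = if (task == "mc") .calibrated$mcAmplitude
                           else .calibrated$rayleighAmplitude),
    signal = list(signal_length = 5:9, blur_sigma = 1.375,
                  amplitude = .calibrated$signalAmplitude),
    mc = list(canvas_size = 200L, n_mcs_range = c(8L, 16L),
              cluster_radius = 25, mc_size_range = c(1.5, 4),
              contrast_range = c(0.05, 0.06), rotation_range = c(0, 360)),
    degradation = list(
      blur_sigma = 1.5,
      downsample_factor = if (task == "mc") 2L else 1L,
      upsample_back = task == "mc"),
    noise = list(
      poisson_scale = if (task == "mc") 1e-4 else 0.013,
      gaussian_std = if (task == "mc") 1e-3 else 0.35,
      poisson_rate = 10),
    observer = list(crop = 64L, lambda_grid = 10^seq(-9, -4),
                    gabor_channels = 60L),
    training = list(n_train = 2000L, n_val = 200L, batch_size = 32L,
                    learning_rate = 1e-3, max_epochs = 10L,
                    semionline_noise = FALSE, flip_augment = task == "mc"),
    peak = if (task == "mc") .calibrated$mcPeak else "auto",
    output = list(dir = ".")
  )
}

## intensity calibrations frozen in the default configuration: the CLB
## amplitude per task (anchoring the printed LR-vs-HR ensemble MSE of each
## study), the Rayleigh signal amplitude, and the PSNR peak reference
## implied by the printed MC-task MSE/PSNR pair.
.calibrated <- list(
  rayleighAmplitude = 2.802,
  signalAmplitude = 10,
  mcAmplitude = 1.764,
  mcPeak = 128.5
)

#' Default experiment configuration
#'
#' Returns the full nested configuration for a task with every default
#' filled in: the standard CLB texture parameters, the per-task degradation
#' and noise models, the observer settings (64 px central crop, 60-channel
#' Gabor bank, lambda decade grid 1e-9..1e-4) and the calibrated intensity
#' scales.
#'
#' @param task "rayleigh" or "mc".
#' @return a named nested list.
#' @export
defaultExperimentConfig <- function(task = c("rayleigh", "mc")) {
  .default_config(match.arg(task))
}

.check_config_keys <- function(cfg, defaults, path = "") {
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "))
  }
  for (k in names(cfg)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      if (!is.list(cfg[[k]])) stop("config key ", path, k, " must be a mapping")
      .check_config_keys(cfg[[k]], defaults[[k]], paste0(path, k, "."))
    }
  }
  invisible(TRUE)
}

.validate_config <- function(cfg) {
  with(cfg$clb, {
    for (nm in c("mean_clusters", "mean_blobs", "half_axis_x", "half_axis_y",
                 "alpha", "beta", "cluster_spread", "field_size",
                 "amplitude")) {
      v <- cfg$clb[[nm]]
      if (!is.numeric(v) || v <= 0) {
        stop("config field clb.", nm, " must be positive")
      }
    }
  })
  if (any(cfg$noise$poisson_scale < 0) || any(cfg$noise$gaussian_std < 0)) {
    stop("config noise scales must be non-negative")
  }
  if (!cfg$task %in% c("rayleigh", "mc")) {
    stop("config field task must be rayleigh or mc")
  }
  invisible(TRUE)
}

#' Load an experiment configuration from YAML
#'
#' Reads the file, fills unset keys with the task defaults, rejects unknown
#' keys and validates field values.
#'
#' @param path YAML file path.
#' @return the validated nested configuration list.
#' @export
loadExperimentConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  task <- raw$task %||% "rayleigh"
  defaults <- .default_config(task)
  .check_config_keys(raw, defaults)
  cfg <- modifyList(defaults, raw)
  if (identical(cfg$peak, "auto")) cfg$peak <- "auto"
  .validate_config(cfg)
  cfg
}

#' Save an experiment configuration to YAML
#'
#' @param cfg configuration list.
#' @param path output YAML path.
#' @return the path, invisibly.
#' @export
saveExperimentConfig <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Materialize spec objects from a configuration
#'
#' @param cfg a configuration list.
#' @return list with \code{clb}, \code{signal} or \code{mc},
#'   \code{degradation}, \code{noise} spec objects.
#' @export
configSpecs <- function(cfg) {
  out <- list(
    clb = clbParams(cfg$clb$mean_clusters, cfg$clb$mean_blobs,
                    cfg$clb$half_axis_x, cfg$clb$half_axis_y, cfg$clb$alpha,
                    cfg$clb$beta, cfg$clb$cluster_spread,
                    cfg$clb$field_size, cfg$clb$amplitude),
    degradation = new("DegradationSpec",
                      blurSigma = cfg$degradation$blur_sigma,
                      downsampleFactor =
                        as.integer(cfg$degradation$downsample_factor),
                      upsampleBack = cfg$degradation$upsample_back,
                      task = cfg$task),
    noise = new("NoiseSpec", poissonScale = cfg$noise$poisson_scale,
                gaussianStd = cfg$noise$gaussian_std,
                poissonRate = cfg$noise$poisson_rate)
  )
  if (cfg$task == "rayleigh") {
    out$signal <- rayleighSignalSpec(cfg$signal$signal_length[1],
                                     cfg$signal$blur_sigma,
                                     cfg$signal$amplitude)
    out$signalLengths <- as.integer(cfg$signal$signal_length)
  } else {
    out$mc <- mcClusterSpec(cfg$mc$canvas_size, cfg$mc$n_mcs_range,
                            cfg$mc$cluster_radius, cfg$mc$mc_size_range,
                            cfg$mc$contrast_range, cfg$mc$rotation_range)
  }
  out
}

#' Write an imaging ensemble to disk
#'
#' The ensemble is serialized (native R serialization) next to a JSON
#' sidecar holding the resolution class, label counts and an md5 content
#' hash, so stored datasets are self-describing and mutation-detectable.
#'
#' @param ens an \code{\link{ImagingEnsemble}}.
#' @param path output path (".rds" appended if missing).
#' @return the manifest entry (list), invisibly.
#' @export
writeEnsemble <- function(ens, path) {
  if (!grepl("\\.rds$", path)) path <- paste0(path, ".rds")
  saveRDS(ens, path)
  entry <- list(
    file = basename(path),
    md5 = unname(tools::md5sum(path)),
    nImages = nImages(ens),
    resolutionClass = resolutionClass(ens),
    labels = as.list(table(ens@labels))
  )
  jsonlite::write_json(entry, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(entry)
}

#' Read an imaging ensemble written by \code{writeEnsemble}
#'
#' @param path the ".rds" path.
#' @param verify check the md5 recorded in the JSON sidecar.
#' @return the \code{\link{ImagingEnsemble}}.
#' @export
readEnsemble <- function(path, verify = TRUE) {
  if (!grepl("\\.rds$", path)) path <- paste0(path, ".rds")
  side <- paste0(path, ".json")
  if (verify && file.exists(side)) {
    entry <- jsonlite::read_json(side)
    if (!identical(unname(tools::md5sum(path))[[1]], entry$md5)) {
      stop("ensemble file hash mismatch: ", path)
    }
  }
  readRDS(path)
}

#' Export a single image to PNG
#'
#' The image is min-max scaled to [0, 1]; the applied scale and offset are
#' returned so intensities remain recoverable.
#'
#' @param img matrix or \code{\link{ObjectImage}}.
#' @param path output PNG path.
#' @return list with \code{path}, \code{offset}, \code{scale}, invisibly.
#' @export
writeImagePNG <- function(img, path) {
  px <- if (is(img, "ObjectImage")) img@pixels else img
  lo <- min(px)
  hi <- max(px)
  scl <- if (hi > lo) hi - lo else 1
  png::writePNG((px - lo) / scl, path)
  invisible(list(path = path, offset = lo, scale = scl))
}

#' Generate deterministic miniature fixture datasets
#'
#' Writes small class-balanced HR/LR ensembles for both tasks (64 px
#' fields, CLB density scaled with field area) plus a manifest with md5
#' hashes; intended for quick end-to-end runs and continuous testing.
#'
#' @param size "tiny" (8 per class) or "small" (32 per class).
#' @param seed master seed.
#' @param dir output directory (created if needed).
#' @return the manifest list, invisibly; written as manifest.json.
#' @export
makeFixtures <- function(size = c("tiny", "small"), seed = 1L,
                         dir = tempfile("fixtures")) {
  size <- match.arg(size)
  n <- if (size == "tiny") 8L else 32L
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  clb64 <- clbParams(meanClusters = 150 / 4, fieldSize = 64L,
                     amplitude = .calibrated$rayleighAmplitude)
  entries <- list()
  ray <- buildTaskEnsembles(
    "rayleigh", n,
    specs = list(clb = clb64,
                 signal = rayleighSignalSpec(7L)),
    seed = seedStream(seed, "fixtures", 1L))
  entries$rayleigh_hr <- writeEnsemble(ray$hr, file.path(dir, "rayleigh_hr"))
  entries$rayleigh_lr <- writeEnsemble(ray$lr, file.path(dir, "rayleigh_lr"))
  clb64mc <- clbParams(meanClusters = 150 / 4, fieldSize = 64L,
                       amplitude = .calibrated$mcAmplitude)
  mc <- buildTaskEnsembles(
    "mc", n,
    specs = list(clb = clb64mc,
                 mc = mcClusterSpec(clusterRadius = 15)),
    seed = seedStream(seed, "fixtures", 2L))
  entries$mc_hr <- writeEnsemble(mc$hr, file.path(dir, "mc_hr"))
  entries$mc_lr <- writeEnsemble(mc$lr, file.path(dir, "mc_lr"))
  manifest <- list(size = size, seed = seed, created = as.character(Sys.time()),
                   entries = entries)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Verify a fixture manifest
#'
#' @param dir fixture directory containing manifest.json.
#' @return TRUE if every stored file matches its recorded hash; otherwise
#'   an error naming the first mismatching file.
#' @export
verifyManifest <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  for (e in manifest$entries) {
    f <- file.path(dir, e$file)
    if (!file.exists(f)) stop("missing fixture file: ", e$file)
    if (!identical(unname(tools::md5sum(f))[[1]], e$md5)) {
      stop("fixture hash mismatch: ", e$file)
    }
  }
  TRUE
}
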