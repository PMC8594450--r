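## Generics, accessors and show methods.

#' @export
setGeneric("images", function(x) standardGeneric("images"))
#' @export
setGeneric("labels2", function(x) standardGeneric("labels2"))
#' @export
setGeneric("resolutionClass", function(x) standardGeneric("resolutionClass"))
#' @export
setGeneric("nImages", function(x) standardGeneric("nImages"))
#' @export
setGeneric("generationSpec", function(x) standardGeneric("generationSpec"))
#' @export
setGeneric("templateWeights", function(x) standardGeneric("templateWeights"))
#' @export
setGeneric("observerKind", function(x) standardGeneric("observerKind"))
#' @export
setGeneric("channelMatrix", function(x) standardGeneric("channelMatrix"))
#' @export
setGeneric("scoresH0", function(x) standardGeneric("scoresH0"))
#' @export
setGeneric("scoresH1", function(x) standardGeneric("scoresH1"))
#' @export
setGeneric("auc", function(x) standardGeneric("auc"))
#' @export
setGeneric("confint2", function(x) standardGeneric("confint2"))
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @export
setGeneric("hypothesis", function(x) standardGeneric("hypothesis"))
#' @export
setGeneric("sweepTable", function(x) standardGeneric("sweepTable"))

#' Accessors for pipeline objects
#'
#' Small accessor family: \code{images}/\code{labels2}/\code{resolutionClass}
#' for ensembles, \code{pixels}/\code{hypothesis} for single images,
#' \code{templateWeights}/\code{observerKind} for linear templates,
#' \code{scoresH0}/\code{scoresH1} for score sets, \code{auc}/\code{confint2}
#' for ROC results and \code{sweepTable} for sweep results.
#' (\code{labels2}/\code{confint2} avoid clobbering the base generics.)
#'
#' @param x the object.
#' @return the slot value.
#' @name accessors
#' @aliases images labels2 resolutionClass nImages generationSpec
#'   templateWeights observerKind channelMatrix scoresH0 scoresH1 auc
#'   confint2 pixels hypothesis sweepTable
NULL

#' @rdname accessors
#' @export
setMethod("images", "ImagingEnsemble", function(x) x@images)
#' @rdname accessors
#' @export
setMethod("labels2", "ImagingEnsemble", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("resolutionClass", "ImagingEnsemble", function(x) x@resolutionClass)
#' @rdname accessors
#' @export
setMethod("nImages", "ImagingEnsemble", function(x) dim(x@images)[3])
#' @rdname accessors
#' @export
setMethod("generationSpec", "ImagingEnsemble", function(x) x@generationSpec)
#' @rdname accessors
#' @export
setMethod("pixels", "ObjectImage", function(x) x@pixels)
#' @rdname accessors
#' @export
setMethod("hypothesis", "ObjectImage", function(x) x@hypothesis)
#' @rdname accessors
#' @export
setMethod("templateWeights", "LinearTemplate", function(x) x@weights)
#' @rdname accessors
#' @export
setMethod("observerKind", "LinearTemplate", function(x) x@kind)
#' @rdname accessors
#' @export
setMethod("channelMatrix", "ChannelMatrix", function(x) x@mat)
#' @rdname accessors
#' @export
setMethod("scoresH0", "ScoreSet", function(x) x@scoresH0)
#' @rdname accessors
#' @export
setMethod("scoresH1", "ScoreSet", function(x) x@scoresH1)
#' @rdname accessors
#' @export
setMethod("auc", "ROCResult", function(x) x@auc)
#' @rdname accessors
#' @export
setMethod("confint2", "ROCResult", function(x) c(x@ciLow, x@ciHigh))
#' @rdname accessors
#' @export
setMethod("sweepTable", "SweepResult", function(x) x@table)

#' Subset an imaging ensemble
#'
#' @param x an \code{ImagingEnsemble}.
#' @param i image indices.
#' @param j,...,drop ignored.
#' @return an \code{ImagingEnsemble} with the selected images.
#' @export
setMethod("[", "ImagingEnsemble", function(x, i, j, ..., drop = FALSE) {
  new("ImagingEnsemble",
      images = x@images[, , i, drop = FALSE],
      labels = factor(as.character(x@labels[i]), levels = c("H0", "H1")),
      resolutionClass = x@resolutionClass,
      generationSpec = x@generationSpec)
})

setMethod("show", "ImagingEnsemble", function(object) {
  d <- dim(object@images)
  cat(sprintf("ImagingEnsemble: %d images (%dx%d), class %s\n",
              d[3], d[1], d[2], object@resolutionClass))
  cat(sprintf("  labels: %d H0 / %d H1\n",
              sum(object@labels == "H0"), sum(object@labels == "H1")))
})

setMethod("show", "ObjectImage", function(object) {
  cat(sprintf("ObjectImage: %dx%d, role=%s, hypothesis=%s\n",
              nrow(object@pixels), ncol(object@pixels), object@role,
              object@hypothesis))
})

setMethod("show", "CovarianceModel", function(object) {
  cat(sprintf(
    "CovarianceModel: dimension %d, n = %d/%d per class, crop = %s\n",
    length(object@meanH0), object@nPerClass[1], object@nPerClass[2],
    ifelse(is.na(object@crop), "none", object@crop)))
  cat(sprintf("  SVD: %s\n",
              if (length(object@svd)) "computed" else "not yet computed"))
})

setMethod("show", "LinearTemplate", function(object) {
  cat(sprintf("LinearTemplate (%s): %d weights", object@kind,
              length(object@weights)))
  if (!is.na(object@lambda)) {
    cat(sprintf(", lambda = %g, retained modes = %d", object@lambda,
                object@retainedModes))
  }
  cat("\n")
})

setMethod("show", "ScoreSet", function(object) {
  cat(sprintf("ScoreSet [%s]: %d H0 / %d H1 scores\n", object@observerId,
              length(object@scoresH0), length(object@scoresH1)))
})

setMethod("show", "ROCResult", function(object) {
  cat(sprintf("AUC = %.4f (%d%% CI %.4f-%.4f, DeLong)%s\n", object@auc,
              round(100 * object@level), object@ciLow, object@ciHigh,
              if (object@degenerate) " [degenerate]" else ""))
})

setMethod("show", "IQMetrics", function(object) {
  cat(sprintf(
    "IQMetrics over %d images: MSE = %.4f, PSNR = %.4f dB, SSIM = %.4f (peak %.4g)\n",
    object@nImages, object@ensembleMSE, object@psnr, object@ssim,
    object@peak))
})

setMethod("show", "SweepResult", function(object) {
  cat(sprintf("SweepResult over %s: %d cells\n", object@axis,
              nrow(object@table)))
  print(head(object@table, 12))
})

setMethod("show", "ConvNetModel", function(object) {
  np <- sum(vapply(rapply(object@params, length, how = "unlist"),
                   identity, numeric(1)))
  cat(sprintf("ConvNetModel (%s): %d parameters, %s\n", object@kind, np,
              if (object@trained) "trained" else "untrained"))
})
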