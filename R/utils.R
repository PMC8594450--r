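## Seeding discipline and small shared helpers.

.stream_index <- c(
  clb = 1L, signal = 2L, mc = 3L, noise = 4L, shuffle = 5L, init = 6L,
  training = 7L, misc = 8L, fixtures = 9L
)

#' Derive a named child seed from a master seed
#'
#' Every source of randomness in the pipeline draws from a named stream
#' (clb, signal, mc, noise, shuffle, init, training, ...), each with a seed
#' derived deterministically from the master seed by a counter-based mixing
#' map.  Adding a stream never perturbs the others, and `offset` lets a
#' driver derive per-image or per-level sub-seeds within a stream.
#'
#' @param master integer master seed.
#' @param stream stream name (see names of valid streams in the error
#'   message).
#' @param offset non-negative integer sub-index within the stream.
#' @return an integer seed in [1, 2^31 - 2].
#' @export
seedStream <- function(master, stream, offset = 0L) {
  if (!stream %in% names(.stream_index)) {
    stop("unknown seed stream '", stream, "'; valid streams: ",
         paste(names(.stream_index), collapse = ", "))
  }
  idx <- .stream_index[[stream]]
  m <- 2147483647  # 2^31 - 1, prime
  x <- (as.double(master) %% m)
  x <- (x * 48271 + 7919 * idx) %% m
  x <- (x * 48271 + 104729 * (as.double(offset) + 1)) %% m
  as.integer(x %% (m - 2) + 1)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so seeded helpers do not
#' perturb the global random stream.
#'
#' @param seed integer seed, or NULL to use the current RNG state.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Central crop of a square image
#'
#' For even sizes the crop window starts at index (N - size)/2 (0-based,
#' half-open), i.e. the centered block.
#'
#' @param img numeric matrix.
#' @param size crop side; NULL or NA returns the input unchanged.
#' @return the cropped matrix.
#' @export
centralCrop <- function(img, size) {
  if (is.null(size) || is.na(size)) return(img)
  n <- nrow(img)
  if (size > n) stop("crop size exceeds image size")
  s <- floor((n - size) / 2) + 1L
  img[s:(s + size - 1L), s:(s + size - 1L), drop = FALSE]
}

## crop every image of a (H, W, N) array and vectorize to (N, d)
.crop_and_flatten <- function(arr, crop = NULL) {
  n <- dim(arr)[3]
  if (!is.null(crop) && !is.na(crop)) {
    sz <- crop
    s <- floor((dim(arr)[1] - sz) / 2) + 1L
    arr <- arr[s:(s + sz - 1L), s:(s + sz - 1L), , drop = FALSE]
  }
  d <- dim(arr)[1] * dim(arr)[2]
  t(matrix(arr, nrow = d, ncol = n))
}

.assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
    stop(name, " must be a positive finite scalar")
  }
  invisible(TRUE)
}
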