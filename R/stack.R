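#' Image stack for one field of view
#'
#' Holds the `F` co-registered grayscale images of one FOV (one per barcode
#' bit), either raw or after band-pass filtering.
#'
#' @param images List of `F` numeric `n x n` matrices, page `f` = bit `f`.
#' @param fov_id FOV identifier.
#' @param z_index Integer z-plane index (0-based).
#' @param is_filtered Logical; `TRUE` once band-pass filtered. Guards against
#'   double filtering.
#' @return An `image_stack` object.
#' @export
image_stack <- function(images, fov_id = 0L, z_index = 0L, is_filtered = FALSE) {
  if (!is.list(images) || length(images) == 0L) {
    stop("`images` must be a non-empty list of matrices")
  }
  dims <- vapply(images, dim, integer(2))
  if (any(dims != dims[1, 1])) {
    stop("all images must be square and share the same n x n shape")
  }
  structure(
    list(
      images = lapply(images, unname),
      n = dims[1, 1],
      fov_id = fov_id,
      z_index = as.integer(z_index),
      is_filtered = isTRUE(is_filtered)
    ),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf(
    "<image_stack> fov %s z %d: %d images %dx%d (%s)\n",
    format(x$fov_id), x$z_index, length(x$images), x$n, x$n,
    if (x$is_filtered) "filtered" else "raw"
  ))
  invisible(x)
}

#' Vectorize an image stack into the Nl x F data matrix
#'
#' Column `f` of the result is image `f` flattened in row-major order (row
#' index varies slowest), the single vectorization convention used throughout
#' the package. The inverse is [devectorize_stack()].
#'
#' @param stack An `image_stack`.
#' @return An `Nl x F` numeric matrix.
#' @export
vectorize_stack <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  matrix(
    vapply(stack$images, function(im) as.vector(t(im)), numeric(stack$n^2)),
    nrow = stack$n^2
  )
}

#' Reassemble an image stack from its vectorized matrix
#'
#' @param Y `Nl x F` matrix as produced by [vectorize_stack()].
#' @param n Image side length; `Nl` must equal `n^2`.
#' @param ... Passed to [image_stack()] (`fov_id`, `z_index`, `is_filtered`).
#' @export
devectorize_stack <- function(Y, n, ...) {
  Y <- as.matrix(Y)
  if (nrow(Y) != n^2) stop("nrow(Y) must equal n^2")
  image_stack(
    lapply(seq_len(ncol(Y)), function(f) matrix(Y[, f], n, n, byrow = TRUE)),
    ...
  )
}

#' Write an image stack to multi-page TIFF
#'
#' Pages are stored as 32-bit samples scaled into \[0, 1\] by the stack
#' maximum; the scale factor is stored in a plain-text sidecar `<path>.scale`
#' so [read_stack()] restores physical intensities (exact to ~2^-32 of full
#' scale).
#'
#' @param stack An `image_stack`.
#' @param path Output TIFF path.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  lo <- min(vapply(stack$images, min, 0))
  hi <- max(vapply(stack$images, max, 0))
  if (lo < 0) stop("TIFF export requires nonnegative intensities")
  scale <- max(hi, .Machine$double.eps)
  tiff::writeTIFF(lapply(stack$images, function(im) im / scale), path,
                  bits.per.sample = 32L, compression = "none")
  writeLines(format(scale, digits = 17), paste0(path, ".scale"))
  invisible(path)
}

#' Read an image stack from multi-page TIFF
#'
#' If a `<path>.scale` sidecar (written by [write_stack()]) exists, pixel
#' values are multiplied by it; otherwise integer TIFFs are read as raw counts.
#'
#' @param path TIFF path.
#' @param ... Passed to [image_stack()].
#' @export
read_stack <- function(path, ...) {
  sidecar <- paste0(path, ".scale")
  if (file.exists(sidecar)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    scale <- as.numeric(readLines(sidecar)[1])
    pages <- lapply(pages, function(p) p * scale)
  } else {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    pages <- lapply(pages, function(p) {
      storage.mode(p) <- "double"
      p
    })
  }
  image_stack(pages, ...)
}
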