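#' Band-pass filter parameters
#'
#' Difference-of-Gaussians (DoG) band-pass prefilter applied to each image
#' before solving: the narrow Gaussian is chosen a little narrower than the
#' microscope PSF and the broad one wider, so the difference suppresses both
#' high-frequency shot noise and the low-frequency autofluorescence background
#' while passing spot-scale structure. Defaults (0.75, 3) px are appropriate
#' for 60x MERFISH data; for other magnifications scale both sigmas by the
#' magnification ratio (e.g. multiply by 60/40 for 40x).
#'
#' @param sigma_narrow Std of the narrow Gaussian (low-res pixels).
#' @param sigma_broad Std of the broad Gaussian (low-res pixels); must exceed
#'   `sigma_narrow`.
#' @param kernel_radius Truncation radius in pixels; default
#'   `ceiling(3 * sigma_broad)` (9 for the default sigmas).
#' @export
bandpass_params <- function(sigma_narrow = 0.75, sigma_broad = 3,
                            kernel_radius = ceiling(3 * sigma_broad)) {
  if (!(sigma_narrow > 0) || !(sigma_broad > sigma_narrow)) {
    stop("need 0 < sigma_narrow < sigma_broad")
  }
  if (kernel_radius < ceiling(3 * sigma_broad)) {
    stop("kernel_radius must be >= ceiling(3 * sigma_broad)")
  }
  structure(
    list(
      sigma_narrow = sigma_narrow,
      sigma_broad = sigma_broad,
      kernel_radius = as.integer(kernel_radius)
    ),
    class = "bandpass_params"
  )
}

#' Difference-of-Gaussians kernel
#'
#' Returns the square kernel of side `2 * kernel_radius + 1` with
#' `kernel[dx, dy] = g(sigma_narrow; r) - g(sigma_broad; r)` where
#' `r = sqrt(dx^2 + dy^2)` and `g(sigma; r)` is the 2-D Gaussian density
#' `exp(-r^2 / (2 sigma^2)) / (2 pi sigma^2)`, renormalized to unit sum over
#' the truncated discrete support. The discrete renormalization makes the
#' kernel sum exactly zero — a constant image filters to exactly zero — at
#' the cost of a small departure (about 4e-4 relative at the defaults) from
#' the analytic density values; without it the truncation tail of the broad
#' Gaussian (~0.5% of its mass at radius 9) would leak the image mean into
#' the output. The kernel is symmetric under reflection and 90-degree
#' rotation.
#'
#' @param params A [bandpass_params()]. Equal sigmas are rejected there; a
#'   hand-built params list with equal sigmas yields the zero kernel.
#' @return Numeric matrix of side `2 * kernel_radius + 1`.
#' @export
dog_kernel <- function(params) {
  r <- params$kernel_radius
  d <- -r:r
  r2 <- outer(d^2, d^2, "+")
  g <- function(sigma) {
    k <- exp(-r2 / (2 * sigma^2)) / (2 * pi * sigma^2)
    k / sum(k)
  }
  if (params$sigma_narrow == params$sigma_broad) {
    return(matrix(0, 2L * r + 1L, 2L * r + 1L))
  }
  g(params$sigma_narrow) - g(params$sigma_broad)
}

# 2-D convolution with reflect padding ("symmetric": edge pixel not repeated
# ... actually reflected including edge, i.e. pad index k mirrors to index k).
conv2_reflect <- function(img, kernel) {
  n1 <- nrow(img); n2 <- ncol(img)
  kr <- (nrow(kernel) - 1L) %/% 2L
  if (nrow(kernel) > n1 || ncol(kernel) > n2) {
    stop("kernel larger than image")
  }
  reflect_idx <- function(n, r) {
    # pad of width r on both sides: mirror across the edge (edge repeated)
    c(rev(seq_len(r)), seq_len(n), n + 1L - seq_len(r))
  }
  pad <- img[reflect_idx(n1, kr), reflect_idx(n2, kr)]
  out <- matrix(0, n1, n2)
  # convolution: out[i,j] = sum_k kernel[k] * pad[i - dk + center]
  for (a in seq_len(nrow(kernel))) {
    dr <- (a - 1L) - kr
    for (b in seq_len(ncol(kernel))) {
      w <- kernel[a, b]
      if (w == 0) next
      dc <- (b - 1L) - kr
      out <- out + w * pad[(kr - dr) + seq_len(n1), (kr - dc) + seq_len(n2)]
    }
  }
  out
}

#' Band-pass filter an image stack
#'
#' Convolves each of the `F` images with the DoG kernel (reflect padding at
#' borders, which avoids the edge darkening zero padding would cause).
#' Filtering must be applied exactly once; a stack with `is_filtered = TRUE`
#' is refused.
#'
#' @param stack A raw `image_stack`.
#' @param params A [bandpass_params()].
#' @return The filtered `image_stack` (`is_filtered = TRUE`). Negative
#'   filtered values are retained; the later hard threshold removes them.
#' @export
bandpass_stack <- function(stack, params = bandpass_params()) {
  stopifnot(inherits(stack, "image_stack"))
  if (stack$is_filtered) {
    stop("stack is already band-pass filtered; filtering is applied exactly once")
  }
  kern <- dog_kernel(params)
  image_stack(
    lapply(stack$images, conv2_reflect, kernel = kern),
    fov_id = stack$fov_id, z_index = stack$z_index, is_filtered = TRUE
  )
}
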