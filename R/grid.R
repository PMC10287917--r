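#' Reconstruction grid geometry
#'
#' Defines the relationship between the camera (low-resolution) pixel grid and
#' the sub-pixel (high-resolution) grid on which molecules are recovered. Each
#' camera pixel is divided into `s^2` equally sized sub-pixels, so an `n x n`
#' image maps to an `(s*n) x (s*n)` recovery grid with `Nh = s^2 * n^2` sites.
#'
#' Vectorization is row-major throughout the package: pixel `(r, c)` (0-based)
#' of an `n x n` image has linear index `r * n + c` (0-based), and the same
#' convention applies on the sub-pixel grid. Low-res pixel `(r, c)` covers
#' sub-pixel rows `s*r .. s*r+s-1` and columns `s*c .. s*c+s-1`; the center of
#' sub-pixel index `i` (per axis) sits at `(i + 0.5)/s - 0.5` in low-res pixel
#' coordinates.
#'
#' @param n Low-res pixels per image side.
#' @param s Integer scale factor (>= 1); each pixel is split into `s^2`
#'   sub-pixels.
#' @param pixel_size Physical size of one low-res pixel, in micrometres.
#' @param z_spacing Separation between z-planes, in micrometres.
#' @return A `grid_spec` object with fields `n`, `s`, `Nl = n^2`,
#'   `Nh = s^2 n^2`, `pixel_size`, `z_spacing`.
#' @examples
#' g <- grid_spec(n = 64, s = 3)
#' g$Nh / g$Nl  # 9 sub-pixels per pixel
#' @export
grid_spec <- function(n, s = 3L, pixel_size = 0.167, z_spacing = 1.5) {
  n <- as.integer(n)
  s <- as.integer(s)
  if (is.na(n) || n <= 0L) stop("`n` must be a positive integer")
  if (is.na(s) || s < 1L) stop("`s` must be an integer >= 1")
  if (!is.numeric(pixel_size) || pixel_size <= 0) {
    stop("`pixel_size` must be > 0")
  }
  structure(
    list(
      n = n, s = s,
      Nl = n * n, Nh = s^2 * n * n,
      pixel_size = pixel_size, z_spacing = z_spacing
    ),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "<grid_spec> n = %d, s = %d (Nl = %d, Nh = %d), pixel %.4g um, dz %.4g um\n",
    x$n, x$s, x$Nl, x$Nh, x$pixel_size, x$z_spacing
  ))
  invisible(x)
}

# row-major linear index (1-based) from 0-based (row, col) on a side-`side` grid
rc_to_index <- function(row, col, side) row * side + col + 1L

# inverse: 0-based (row, col) from 1-based row-major linear index
index_to_rc <- function(idx, side) {
  idx0 <- idx - 1L
  cbind(row = idx0 %/% side, col = idx0 %% side)
}

# center of sub-pixel axis-index i (0-based) in low-res pixel coordinates
subpixel_center <- function(i, s) (i + 0.5) / s - 0.5
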