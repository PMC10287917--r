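#' Point-spread-function sensing matrix
#'
#' `A` is the `Nl x Nh` linear operator taking intensity placed at sub-pixel
#' sites to camera pixel values: entry `(il, ih)` is the fraction of photons
#' emitted at sub-pixel `ih` that lands in pixel `il`. The default constructor
#' composes a truncated isotropic Gaussian blur between sub-pixel centers with
#' `s x s` block-sum downsampling. Kernel weights are point samples of the
#' Gaussian at sub-pixel center offsets, truncated at `truncation_radius`
#' (Euclidean, low-res pixel units) and renormalized so that columns far from
#' every image border sum to exactly 1; border columns keep their truncated
#' (< 1) sums — photons leaving the FOV are lost, as on a physical camera.
#'
#' @param grid A [grid_spec()].
#' @param psf_sigma Gaussian PSF standard deviation in low-res pixel units
#'   (>= 0; 0 gives a delta PSF, i.e. pure downsampling).
#' @param truncation_radius Kernel cutoff in low-res pixel units; default
#'   `3 * psf_sigma`.
#' @return A `sensing_matrix`: sparse `Nl x Nh` values plus construction
#'   metadata.
#' @examples
#' A <- build_sensing_matrix(grid_spec(8, 2), psf_sigma = 0.6)
#' range(Matrix::colSums(A$values))
#' @export
build_sensing_matrix <- function(grid, psf_sigma,
                                 truncation_radius = 3 * psf_sigma) {
  stopifnot(inherits(grid, "grid_spec"))
  if (psf_sigma < 0) stop("`psf_sigma` must be >= 0")
  n <- grid$n
  s <- grid$s
  N <- n * s

  if (psf_sigma == 0) {
    # delta PSF: sub-pixel (R, C) contributes fully to pixel (R %/% s, C %/% s)
    Rg <- rep(0:(N - 1L), each = N)
    Cg <- rep(0:(N - 1L), times = N)
    A <- Matrix::sparseMatrix(
      i = rc_to_index(Rg %/% s, Cg %/% s, n),
      j = rc_to_index(Rg, Cg, N),
      x = 1,
      dims = c(grid$Nl, grid$Nh)
    )
    return(new_sensing_matrix(A, psf_sigma, truncation_radius, grid))
  }
  if (truncation_radius <= 0) stop("`truncation_radius` must be > 0")

  # kernel offsets on the sub-pixel lattice, distances in low-res units
  k <- floor(truncation_radius * s)
  a <- rep(-k:k, times = 2L * k + 1L)
  b <- rep(-k:k, each = 2L * k + 1L)
  d2 <- (a / s)^2 + (b / s)^2
  keep <- d2 <= truncation_radius^2
  a <- a[keep]; b <- b[keep]
  w <- exp(-d2[keep] / (2 * psf_sigma^2))
  w <- w / sum(w) # interior columns sum to 1 after stamping

  Rg <- rep(0:(N - 1L), each = N)
  Cg <- rep(0:(N - 1L), times = N)
  jidx <- rc_to_index(Rg, Cg, N)
  parts_i <- parts_j <- parts_x <- vector("list", length(a))
  for (t in seq_along(a)) {
    Rt <- Rg + a[t]
    Ct <- Cg + b[t]
    ok <- Rt >= 0L & Rt < N & Ct >= 0L & Ct < N
    parts_i[[t]] <- rc_to_index(Rt[ok] %/% s, Ct[ok] %/% s, n)
    parts_j[[t]] <- jidx[ok]
    parts_x[[t]] <- rep.int(w[t], sum(ok))
  }
  A <- Matrix::sparseMatrix(
    i = unlist(parts_i), j = unlist(parts_j), x = unlist(parts_x),
    dims = c(grid$Nl, grid$Nh)
  )
  new_sensing_matrix(A, psf_sigma, truncation_radius, grid)
}

new_sensing_matrix <- function(values, psf_sigma, truncation_radius, grid) {
  structure(
    list(
      values = values,
      psf_sigma = psf_sigma,
      truncation_radius = truncation_radius,
      grid = grid
    ),
    class = "sensing_matrix"
  )
}

#' @export
print.sensing_matrix <- function(x, ...) {
  cat(sprintf(
    "<sensing_matrix> %d x %d, psf_sigma = %.3g px, truncation = %.3g px, nnz = %d\n",
    nrow(x$values), ncol(x$values), x$psf_sigma, x$truncation_radius,
    length(x$values@x)
  ))
  invisible(x)
}

#' Column sums of a sensing matrix
#'
#' Interior columns (sub-pixels farther than the truncation radius from every
#' border) sum to 1; border columns sum to less.
#' @param A A `sensing_matrix`.
#' @export
sensing_column_sums <- function(A) Matrix::colSums(A$values)

# accept either a sensing_matrix or a bare (sparse) matrix
sensing_values <- function(A) {
  if (inherits(A, "sensing_matrix")) A$values else A
}

#' Write a sensing matrix as coordinate triplets
#'
#' Plain-text format: header lines `# Nl <int>`, `# Nh <int>`,
#' `# psf_sigma <num>`, `# truncation_radius <num>`, then one `row col value`
#' triplet per nonzero (1-based indices, full precision).
#' @param A A `sensing_matrix`.
#' @param path Output path.
#' @export
write_sensing_matrix <- function(A, path) {
  stopifnot(inherits(A, "sensing_matrix"))
  T <- methods::as(A$values, "TsparseMatrix")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# Nl %d", nrow(A$values)),
    sprintf("# Nh %d", ncol(A$values)),
    sprintf("# psf_sigma %s", format(A$psf_sigma, digits = 17)),
    sprintf("# truncation_radius %s", format(A$truncation_radius, digits = 17))
  ), con)
  utils::write.table(
    data.frame(i = T@i + 1L, j = T@j + 1L, x = format(T@x, digits = 17)),
    con, row.names = FALSE, col.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Read a sensing matrix written by [write_sensing_matrix()]
#'
#' @param path File path.
#' @param grid Optional [grid_spec()] to attach (checked against the header).
#' @export
read_sensing_matrix <- function(path, grid = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  get_hdr <- function(key) {
    ln <- grep(paste0("^# ", key, " "), lines[hdr], value = TRUE)
    if (length(ln) != 1L) stop(sprintf("missing header `%s` in %s", key, path))
    as.numeric(sub(paste0("^# ", key, " "), "", ln))
  }
  Nl <- as.integer(get_hdr("Nl"))
  Nh <- as.integer(get_hdr("Nh"))
  trip <- utils::read.table(text = lines[-hdr], col.names = c("i", "j", "x"))
  if (any(trip$x < 0)) stop("sensing matrix entries must be nonnegative")
  vals <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = trip$x,
                               dims = c(Nl, Nh))
  if (!is.null(grid) && (grid$Nl != Nl || grid$Nh != Nh)) {
    stop("grid dimensions do not match sensing matrix header")
  }
  new_sensing_matrix(vals, get_hdr("psf_sigma"), get_hdr("truncation_radius"),
                     grid)
}
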