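#' Cell segmentation mask
#'
#' Integer label image for one FOV/z-plane: 0 is background, `k > 0` is cell
#' `k` (ids need not be contiguous). Masks are external inputs (e.g. from a
#' seeded watershed); this package only consumes them.
#'
#' @param labels Integer matrix, either `n x n` (low-res, the default
#'   resolution) or `(s*n) x (s*n)` (high-res).
#' @param fov_id FOV identifier.
#' @param z_index z-plane index.
#' @param fov_origin Absolute (x, y) offset of the FOV upper-left corner, um.
#' @param resolution `"lowres"` or `"highres"`; declares how transcript
#'   sub-pixel coordinates map onto `labels`.
#' @export
segmentation_mask <- function(labels, fov_id = 0L, z_index = 0L,
                              fov_origin = c(0, 0),
                              resolution = c("lowres", "highres")) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  if (any(labels < 0, na.rm = TRUE)) stop("labels must be nonnegative")
  structure(
    list(
      labels = unname(labels),
      fov_id = fov_id,
      z_index = as.integer(z_index),
      fov_origin = as.numeric(fov_origin),
      resolution = match.arg(resolution)
    ),
    class = "segmentation_mask"
  )
}

#' @export
print.segmentation_mask <- function(x, ...) {
  cat(sprintf(
    "<segmentation_mask> fov %s z %d: %dx%d (%s), %d cells\n",
    format(x$fov_id), x$z_index, nrow(x$labels), ncol(x$labels), x$resolution,
    length(setdiff(unique(as.vector(x$labels)), 0L))
  ))
  invisible(x)
}

#' Read a segmentation mask from a single-page integer TIFF
#' @param path TIFF path.
#' @param ... Passed to [segmentation_mask()].
#' @export
read_mask <- function(path, ...) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  segmentation_mask(m, ...)
}

#' Write a segmentation mask to a single-page TIFF
#' @param mask A `segmentation_mask`.
#' @param path Output path.
#' @export
write_mask <- function(mask, path) {
  mx <- max(mask$labels, 1L)
  bits <- if (mx < 256) 8L else 16L
  if (mx >= 2^16) stop("label ids exceed 16-bit TIFF range")
  tiff::writeTIFF(mask$labels / (2^bits - 1), path, bits.per.sample = bits,
                  compression = "none")
  invisible(path)
}

mask_cell_areas <- function(mask) {
  tab <- table(mask$labels[mask$labels > 0L])
  stats::setNames(as.integer(tab), names(tab))
}

#' Reject cells with outlying area
#'
#' Cells with area below half the median or above twice the median cell area
#' are relabeled to background. When a list of masks is given the median is
#' computed over all cells in all masks before any rejection, and every mask
#' is filtered against that common median. The rule is scale-invariant.
#'
#' @param masks A `segmentation_mask` or list of them.
#' @return Filtered mask(s), same shape as the input.
#' @export
filter_cells_by_area <- function(masks) {
  single <- inherits(masks, "segmentation_mask")
  if (single) masks <- list(masks)
  areas <- unlist(lapply(masks, mask_cell_areas))
  if (length(areas) == 0L) {
    warning("no labeled cells in mask(s)")
    return(if (single) masks[[1]] else masks)
  }
  med <- stats::median(areas)
  out <- lapply(masks, function(m) {
    a <- mask_cell_areas(m)
    drop_ids <- as.integer(names(a)[a < med / 2 | a > 2 * med])
    m$labels[m$labels %in% drop_ids] <- 0L
    m
  })
  if (single) out[[1]] else out
}

#' Assign transcript calls to segmented cells
#'
#' A kept call is assigned to the label of the mask pixel containing its
#' rounded centroid (sub-pixel coordinates floor-divided by `s` for low-res
#' masks). Background pixels and centroids outside the mask extent give cell
#' id 0 (unassigned). Calls not marked `"kept"` are never assigned.
#'
#' @param calls Transcript tibble with `passed_filter` set (or all
#'   `"unfiltered"`, in which case all calls are eligible).
#' @param mask A `segmentation_mask`.
#' @param grid The [grid_spec()] of the call coordinates.
#' @return Integer vector of cell ids, one per row of `calls` (0 =
#'   unassigned / not kept).
#' @export
assign_transcripts <- function(calls, mask, grid) {
  stopifnot(inherits(mask, "segmentation_mask"))
  eligible <- calls$passed_filter %in% c("kept", "unfiltered")
  div <- if (mask$resolution == "lowres") grid$s else 1L
  r <- calls$row_px %/% div
  c <- calls$col_px %/% div
  inside <- r >= 0 & r < nrow(mask$labels) & c >= 0 & c < ncol(mask$labels)
  ids <- integer(nrow(calls))
  sel <- eligible & inside
  ids[sel] <- mask$labels[cbind(r[sel] + 1L, c[sel] + 1L)]
  n_outside <- sum(eligible & !inside)
  if (n_outside > 0) {
    attr(ids, "n_outside_mask") <- n_outside
  }
  ids
}

#' Build the cell-by-gene count table
#'
#' Tallies kept, in-cell transcript calls into `S` (cells x genes) and
#' records cell geometry: `area` (mask pixels), absolute positions `L`
#' (`x_um`, `y_um`, `z_um`; mask centroid in um plus the FOV origin) and
#' FOV-relative positions `Lr` (`xr_um`, `yr_um`, `zr_um`). Column sums of
#' `S` conserve the number of assigned kept calls exactly.
#'
#' @param calls Transcript tibble.
#' @param mask A `segmentation_mask` (after any area filtering).
#' @param codebook A [codebook()] fixing the gene columns.
#' @param grid A [grid_spec()] (pixel size, scale factor).
#' @return A `cell_table`: list with integer matrix `S` (`Nc x G`), tibble
#'   `cells` (`cell_id`, `fov`, `z`, `area`, L and Lr columns,
#'   `dist_to_center_px`), and `gene_names`.
#' @export
build_cell_table <- function(calls, mask, codebook, grid) {
  areas <- mask_cell_areas(mask)
  cell_ids <- as.integer(names(areas))
  Nc <- length(cell_ids)
  G <- n_genes(codebook)
  px <- if (mask$resolution == "lowres") grid$pixel_size
        else grid$pixel_size / grid$s
  side <- nrow(mask$labels)
  center <- (side - 1) / 2 # pixel coordinates of FOV center

  # cell centroids: unweighted mean of member pixel centers (0-based px)
  lab <- mask$labels
  nz <- which(lab > 0L, arr.ind = TRUE)
  drow <- nz[, 1] - 1L
  dcol <- nz[, 2] - 1L
  id <- lab[nz]
  crow <- tapply(drow, id, mean)[as.character(cell_ids)]
  ccol <- tapply(dcol, id, mean)[as.character(cell_ids)]

  assigned <- assign_transcripts(calls, mask, grid)
  S <- matrix(0L, Nc, G, dimnames = list(cell_ids, codebook$gene_names))
  use <- assigned > 0L
  if (any(use)) {
    tab <- table(
      factor(assigned[use], levels = cell_ids),
      factor(calls$gene_index[use], levels = seq_len(G))
    )
    S[] <- as.integer(tab)
  }

  xr <- as.numeric(ccol) * px # x = column axis, y = row axis
  yr <- as.numeric(crow) * px
  zr <- rep(mask$z_index * grid$z_spacing, Nc)
  cells <- tibble::tibble(
    cell_id = cell_ids,
    fov = rep(mask$fov_id, Nc),
    z = rep(mask$z_index, Nc),
    area = as.integer(areas),
    x_um = xr + mask$fov_origin[1],
    y_um = yr + mask$fov_origin[2],
    z_um = zr,
    xr_um = xr,
    yr_um = yr,
    zr_um = zr,
    dist_to_center_px = sqrt((as.numeric(crow) - center)^2 +
                             (as.numeric(ccol) - center)^2)
  )
  structure(
    list(S = S, cells = cells, gene_names = codebook$gene_names),
    class = "cell_table"
  )
}

#' @export
print.cell_table <- function(x, ...) {
  cat(sprintf(
    "<cell_table> %d cells x %d genes, %s counts\n",
    nrow(x$S), ncol(x$S), format(sum(x$S))
  ))
  invisible(x)
}

#' Combine cell tables from multiple FOVs / z-planes
#' @param ... `cell_table` objects (or a single list of them).
#' @export
combine_cell_tables <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1L && !inherits(tabs[[1]], "cell_table")) {
    tabs <- tabs[[1]]
  }
  stopifnot(all(vapply(tabs, inherits, TRUE, "cell_table")))
  gn <- tabs[[1]]$gene_names
  stopifnot(all(vapply(tabs, function(t) identical(t$gene_names, gn), TRUE)))
  structure(
    list(
      S = do.call(rbind, lapply(tabs, `[[`, "S")),
      cells = dplyr::bind_rows(lapply(tabs, `[[`, "cells")),
      gene_names = gn
    ),
    class = "cell_table"
  )
}

#' Correct FOV-edge expression bias
#'
#' Optical aberrations depress decoding near FOV edges. Cells (across all
#' FOVs) are binned by their FOV-relative distance to the FOV center into `K`
#' equal-width radial bins; for each gene `g` and bin `k` the mean expression
#' `m_gk` is computed, and counts are rescaled by `s_gk = mean_g / m_gk`
#' (global mean over all cells divided by the bin mean), so that after
#' correction every gene's per-bin mean equals its global mean. Bins with no
#' cells or with `m_gk = 0` get scale 1.
#'
#' @param table A `cell_table` (counts become real-valued after correction).
#' @param K Number of radial bins (>= 1); default 10.
#' @return The corrected `cell_table`, with an `edge_correction` attribute
#'   holding `K`, the per-bin means `m` and the scales applied.
#' @export
fov_edge_correction <- function(table, K = 10L) {
  stopifnot(inherits(table, "cell_table"))
  if (K < 1) stop("`K` must be >= 1")
  d <- table$cells$dist_to_center_px
  edges <- seq(0, max(d) + .Machine$double.eps, length.out = K + 1L)
  bin <- pmin(pmax(findInterval(d, edges, rightmost.closed = TRUE), 1L), K)
  S <- table$S
  storage.mode(S) <- "double"
  G <- ncol(S)
  m <- matrix(NA_real_, G, K)
  scale <- matrix(1, G, K)
  global_mean <- colMeans(S)
  for (k in seq_len(K)) {
    sel <- bin == k
    if (!any(sel)) next
    m[, k] <- colMeans(S[sel, , drop = FALSE])
    nz <- m[, k] > 0
    scale[nz, k] <- global_mean[nz] / m[nz, k]
  }
  table$S <- S * t(scale)[bin, , drop = FALSE]
  attr(table, "edge_correction") <- list(K = K, bin = bin, m = m,
                                         scale = scale, edges = edges)
  table
}
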