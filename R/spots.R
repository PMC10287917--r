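#' Spot-calling parameters
#'
#' @param t_x Hard threshold on recovered intensities (>= 0); entries strictly
#'   below `t_x` are zeroed, entries equal to it kept.
#' @param min_cluster_size Minimum connected-component area `c` in sub-pixels;
#'   clusters smaller than this are rejected as noise. Typical value 2.
#' @param connectivity Pixel connectivity for component labeling, 4 or 8
#'   (default 8, matching the standard 2-D labeling default).
#' @export
spot_params <- function(t_x, min_cluster_size = 2L, connectivity = 8L) {
  if (t_x < 0) stop("`t_x` must be >= 0")
  if (min_cluster_size < 1) stop("`min_cluster_size` must be >= 1")
  if (!connectivity %in% c(4L, 8L)) stop("`connectivity` must be 4 or 8")
  structure(
    list(
      t_x = t_x,
      min_cluster_size = as.integer(min_cluster_size),
      connectivity = as.integer(connectivity)
    ),
    class = "spot_params"
  )
}

#' Keep only the per-row maximum of a solver field
#'
#' Imposes the one-molecule-per-location constraint in post-processing: for
#' every sub-pixel row, all entries except the maximum are set to zero
#' (all-zero rows stay zero). Ties break to the lowest gene index, so results
#' are deterministic.
#'
#' @param X A `molecule_field` at stage `raw_solver`.
#' @return A sparse `molecule_field` at stage `one_sparse`.
#' @export
row_one_sparsify <- function(X) {
  require_stage(X, "raw_solver")
  V <- as.matrix(field_values(X))
  j <- max.col(V, ties.method = "first")
  i <- seq_len(nrow(V))
  v <- V[cbind(i, j)]
  keep <- v != 0
  out <- Matrix::sparseMatrix(i = i[keep], j = j[keep], x = v[keep],
                              dims = dim(V))
  molecule_field(out, X$grid, stage = "one_sparse")
}

#' Hard-threshold a one-sparse field
#'
#' Zeroes entries strictly below `t_x` (strict `<`: values equal to the
#' threshold are retained). Removes low-intensity noise and calls that match
#' the codebook poorly.
#'
#' @param X A `molecule_field` at stage `one_sparse`.
#' @param t_x Threshold (>= 0).
#' @return A `molecule_field` at stage `thresholded`.
#' @export
hard_threshold <- function(X, t_x) {
  require_stage(X, "one_sparse")
  if (t_x < 0) stop("`t_x` must be >= 0")
  V <- field_values(X)
  V <- Matrix::drop0(V * (V >= t_x))
  molecule_field(V, X$grid, stage = "thresholded")
}

# label connected components among nonzero pixels; rc is a 2-column 0-based
# (row, col) matrix. Returns integer component ids (1..k).
label_components <- function(rc, connectivity) {
  m <- nrow(rc)
  if (m == 0L) return(integer(0))
  if (m == 1L) return(1L)
  # neighbor pairs found by hashing pixel coordinates (match is hash-based)
  side <- max(rc) + 2L
  key <- rc[, 1] * side + rc[, 2]
  offs <- if (connectivity == 8L) {
    cbind(dr = c(-1L, -1L, -1L, 0L), dc = c(-1L, 0L, 1L, -1L))
  } else {
    cbind(dr = c(-1L, 0L), dc = c(0L, -1L))
  }
  from <- integer(0); to <- integer(0)
  for (o in seq_len(nrow(offs))) {
    hit <- match((rc[, 1] + offs[o, 1]) * side + rc[, 2] + offs[o, 2], key)
    ok <- !is.na(hit)
    from <- c(from, which(ok))
    to <- c(to, hit[ok])
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, m - igraph::vcount(g)))
  igraph::components(g)$membership
}

round_half_up <- function(x) floor(x + 0.5)

#' Extract transcript calls from a thresholded field
#'
#' For each gene, the field column is reshaped to the sub-pixel image,
#' connected components of nonzero pixels are labeled, components smaller than
#' `min_cluster_size` are dropped, and each surviving cluster becomes one
#' transcript call located at the unweighted centroid of its member pixels
#' (clusters arise because one molecule can light up several adjacent
#' sub-pixels). The cluster's summed pre-binarization intensity and pixel area
#' are recorded for downstream adaptive filtering.
#'
#' @param X A `molecule_field` at stage `thresholded`.
#' @param params A [spot_params()].
#' @param codebook Optional [codebook()] supplying gene names.
#' @param fov_id,z_index Provenance columns for the output.
#' @return A tibble with one row per call: `fov`, `z`, `gene_index`, `gene`,
#'   `row_highres`, `col_highres` (continuous 0-based centroid),
#'   `row_px`, `col_px` (centroid rounded half-up), `area`, `intensity`,
#'   `passed_filter` (initially `"unfiltered"`).
#' @export
extract_transcripts <- function(X, params, codebook = NULL,
                                fov_id = 0L, z_index = 0L) {
  require_stage(X, "thresholded")
  stopifnot(inherits(params, "spot_params"))
  V <- methods::as(field_values(X), "TsparseMatrix")
  N <- X$grid$n * X$grid$s
  out <- vector("list", ncol(V))
  for (g in seq_len(ncol(V))) {
    sel <- V@j + 1L == g
    if (!any(sel)) next
    idx <- V@i[sel] + 1L # row-major linear index (1-based)
    val <- V@x[sel]
    rc <- index_to_rc(idx, N)
    comp <- label_components(rc, params$connectivity)
    sizes <- tabulate(comp)
    keep <- which(sizes >= params$min_cluster_size)
    if (length(keep) == 0L) next
    rows <- vapply(keep, function(k) mean(rc[comp == k, 1]), 0)
    cols <- vapply(keep, function(k) mean(rc[comp == k, 2]), 0)
    out[[g]] <- tibble::tibble(
      gene_index = g,
      row_highres = rows,
      col_highres = cols,
      row_px = round_half_up(rows),
      col_px = round_half_up(cols),
      area = sizes[keep],
      intensity = vapply(keep, function(k) sum(val[comp == k]), 0)
    )
  }
  calls <- dplyr::bind_rows(out)
  if (nrow(calls) == 0L) {
    calls <- tibble::tibble(
      gene_index = integer(), row_highres = numeric(), col_highres = numeric(),
      row_px = numeric(), col_px = numeric(), area = integer(),
      intensity = numeric()
    )
  }
  gene_names <- if (!is.null(codebook)) codebook$gene_names[calls$gene_index]
                else as.character(calls$gene_index)
  tibble::tibble(
    fov = rep(fov_id, nrow(calls)),
    z = rep(as.integer(z_index), nrow(calls)),
    gene_index = calls$gene_index,
    gene = gene_names,
    calls[c("row_highres", "col_highres", "row_px", "col_px",
            "area", "intensity")],
    passed_filter = rep("unfiltered", nrow(calls))
  )
}

#' Binarized field of rounded call locations
#'
#' Builds the final stage of the spot chain: value 1 at each call's rounded
#' centroid, 0 elsewhere.
#'
#' @param calls Transcript tibble from [extract_transcripts()].
#' @param grid A [grid_spec()].
#' @param G Number of genes (columns).
#' @return A `molecule_field` at stage `binarized`.
#' @export
binarize_field <- function(calls, grid, G) {
  N <- grid$n * grid$s
  V <- Matrix::sparseMatrix(
    i = rc_to_index(calls$row_px, calls$col_px, N),
    j = calls$gene_index,
    x = rep(1, nrow(calls)),
    dims = c(grid$Nh, G)
  )
  V@x[] <- 1 # duplicate centroids collapse to 1, not a sum
  molecule_field(V, grid, stage = "binarized")
}
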