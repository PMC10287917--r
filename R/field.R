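#' Recovered molecule field
#'
#' The `Nh x G` matrix X whose nonzero entries give the intensity and gene
#' identity of recovered molecules on the sub-pixel grid. A field carries a
#' processing `stage` so that the spot-calling chain (one-sparsify, hard
#' threshold, extract) can only be run in order:
#' `raw_solver -> one_sparse -> thresholded -> binarized`.
#'
#' @param values `Nh x G` matrix (base or `Matrix` sparse).
#' @param grid The [grid_spec()] the rows index.
#' @param stage One of `"raw_solver"`, `"one_sparse"`, `"thresholded"`,
#'   `"binarized"`.
#' @return A `molecule_field`.
#' @export
molecule_field <- function(values, grid,
                           stage = c("raw_solver", "one_sparse",
                                     "thresholded", "binarized")) {
  stage <- match.arg(stage)
  stopifnot(inherits(grid, "grid_spec"))
  if (nrow(values) != grid$Nh) stop("nrow(values) must equal grid$Nh")
  structure(
    list(values = values, grid = grid, stage = stage),
    class = "molecule_field"
  )
}

#' @export
print.molecule_field <- function(x, ...) {
  nz <- Matrix::nnzero(x$values)
  cat(sprintf(
    "<molecule_field> %d x %d (stage %s, %d nonzero)\n",
    nrow(x$values), ncol(x$values), x$stage, nz
  ))
  invisible(x)
}

field_values <- function(X) {
  if (inherits(X, "molecule_field")) X$values else X
}

require_stage <- function(X, stage) {
  if (!inherits(X, "molecule_field")) {
    stop("expected a `molecule_field`")
  }
  if (X$stage != stage) {
    stop(sprintf("field is at stage `%s`; expected `%s` (pipeline order is raw_solver -> one_sparse -> thresholded -> binarized)",
                 X$stage, stage))
  }
  invisible(X)
}

#' Noiseless forward model Y = A X C
#'
#' Maps a molecule field through the optical blur `A` and the codebook `C`:
#' the result's column `f` is the vectorized noiseless image of round `f`.
#' Linear in `X`.
#'
#' @param X A `molecule_field` or bare `Nh x G` matrix.
#' @param A A `sensing_matrix` or bare `Nl x Nh` matrix.
#' @param C A `codebook` or bare `G x F` binary matrix.
#' @return Dense `Nl x F` matrix.
#' @export
forward_model <- function(X, A, C) {
  Xv <- field_values(X)
  Av <- sensing_values(A)
  Cv <- if (inherits(C, "codebook")) codebook_matrix(C) else C
  if (ncol(Av) != nrow(Xv)) {
    stop(sprintf("A has %d columns but X has %d rows", ncol(Av), nrow(Xv)))
  }
  if (ncol(Xv) != nrow(Cv)) {
    stop(sprintf("X has %d columns but C has %d rows", ncol(Xv), nrow(Cv)))
  }
  as.matrix(Av %*% Xv %*% Cv)
}
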