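#' Solver parameters for the sparse-group-LASSO decoding problem
#'
#' The decoding objective is
#' \deqn{\|Y_f - A X C\|_F^2 + \lambda_1 (1-\lambda_2) \sum_i \|X_{i,\cdot}\|_2
#'       + \lambda_1 \lambda_2 \|X\|_1,}
#' a convex mix of a per-row (per-location) group penalty — molecules occupy
#' few locations — and an elementwise l1 penalty — the field is overall
#' sparse. `lambda2 = 1` reduces to plain LASSO, `lambda2 = 0` to the pure
#' group LASSO.
#'
#' @param lambda1 Overall regularization weight (>= 0).
#' @param lambda2 Mix between l1 and group terms, in \[0, 1\]; default 0.5.
#' @param max_iters Maximum FISTA iterations.
#' @param rel_tol Relative objective-change stopping tolerance (checked every
#'   10 iterations on the full objective).
#' @param step_size Step size 1/L, or `NULL` to estimate via power iteration.
#' @param nonneg If `TRUE`, project iterates onto X >= 0 inside the prox. The
#'   default solves the unconstrained problem; negatives are removed later by
#'   the hard threshold.
#' @export
solver_params <- function(lambda1, lambda2 = 0.5, max_iters = 200L,
                          rel_tol = 1e-6, step_size = NULL, nonneg = FALSE) {
  if (lambda1 < 0) stop("`lambda1` must be >= 0")
  if (lambda2 < 0 || lambda2 > 1) stop("`lambda2` must be in [0, 1]")
  if (max_iters < 1) stop("`max_iters` must be >= 1")
  if (rel_tol <= 0) stop("`rel_tol` must be > 0")
  structure(
    list(
      lambda1 = lambda1, lambda2 = lambda2,
      max_iters = as.integer(max_iters), rel_tol = rel_tol,
      step_size = step_size, nonneg = isTRUE(nonneg)
    ),
    class = "solver_params"
  )
}

as_C_matrix <- function(C) if (inherits(C, "codebook")) codebook_matrix(C) else C

#' Decoding objective value
#'
#' @param X `Nh x G` matrix (or `molecule_field`).
#' @param Yf Filtered, vectorized `Nl x F` data matrix.
#' @param A Sensing matrix (or bare matrix).
#' @param C Codebook (or bare `G x F` matrix).
#' @param params A [solver_params()].
#' @return Scalar objective value (always >= 0).
#' @export
sgl_objective <- function(X, Yf, A, C, params) {
  Xv <- field_values(X)
  resid <- forward_model(Xv, A, C) - Yf
  fit <- sum(resid^2)
  if (params$lambda1 == 0) return(fit)
  row_norms <- sqrt(Matrix::rowSums(Xv^2))
  fit +
    params$lambda1 * (1 - params$lambda2) * sum(row_norms) +
    params$lambda1 * params$lambda2 * sum(abs(Xv))
}

#' Gradient of the data-fit term
#'
#' Gradient of `||Yf - A X C||_F^2` in X: `2 A' (A X C - Yf) C'`.
#' @inheritParams sgl_objective
#' @return Dense `Nh x G` matrix.
#' @export
gradient_datafit <- function(X, Yf, A, C) {
  Xv <- field_values(X)
  Av <- sensing_values(A)
  Cv <- as_C_matrix(C)
  resid <- Av %*% Xv %*% Cv - Yf
  as.matrix(2 * Matrix::crossprod(Av, resid %*% t(Cv)))
}

#' Proximal operator of the sparse-group penalty
#'
#' Row-separable exact minimizer of
#' `0.5 ||x - v||^2 + tau * lambda1 * lambda2 * ||x||_1 +
#'  tau * lambda1 * (1 - lambda2) * ||x||_2` per row: entrywise
#' soft-threshold by `tau * lambda1 * lambda2`, then group shrinkage
#' `u -> max(0, 1 - tau * lambda1 * (1 - lambda2) / ||u||_2) * u`.
#'
#' @param V Input matrix (rows are locations, columns genes).
#' @param tau Step size (> 0).
#' @param lambda1,lambda2 Penalty weights as in [solver_params()].
#' @param nonneg If `TRUE`, clamp negatives to zero before shrinking
#'   (projection onto the nonnegative orthant composed with the prox).
#' @return Matrix of the same shape.
#' @export
prox_sparse_group <- function(V, tau, lambda1, lambda2, nonneg = FALSE) {
  if (tau <= 0) stop("`tau` must be > 0")
  if (nonneg) V <- pmax(V, 0)
  if (lambda1 == 0) return(V)
  soft <- tau * lambda1 * lambda2
  U <- sign(V) * pmax(abs(V) - soft, 0)
  grp <- tau * lambda1 * (1 - lambda2)
  if (grp > 0) {
    rn <- sqrt(rowSums(U^2))
    scale <- ifelse(rn > 0, pmax(0, 1 - grp / rn), 0)
    U <- U * scale
  }
  U
}

#' Estimate the FISTA step size 1/L
#'
#' The data-fit gradient is Lipschitz with constant
#' `L = 2 * sigma_max(A)^2 * sigma_max(C)^2`; both spectral norms are
#' estimated by power iteration to 1e-4 relative tolerance. The returned step
#' is `1 / L`.
#'
#' @param A Sensing matrix (or bare matrix).
#' @param C Codebook (or bare matrix).
#' @param seed Seed for the power-iteration start vectors (the only source of
#'   randomness in the solver).
#' @export
estimate_step <- function(A, C, seed = 1L) {
  Av <- sensing_values(A)
  Cv <- as_C_matrix(C)
  sa <- spectral_norm(Av, seed)
  sc <- spectral_norm(Cv, seed + 1L)
  if (sa == 0 || sc == 0) stop("zero operator: cannot estimate a step size")
  1 / (2 * sa^2 * sc^2)
}

# power iteration on M'M; returns sigma_max(M)
spectral_norm <- function(M, seed, tol = 1e-4, max_iter = 500L) {
  set.seed(seed)
  v <- stats::rnorm(ncol(M))
  v <- v / sqrt(sum(v^2))
  ev <- 0
  for (i in seq_len(max_iter)) {
    w <- as.numeric(Matrix::crossprod(M, M %*% v))
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(0)
    v_new <- w / nw
    ev_new <- nw # Rayleigh-quotient-free estimate: ||M'M v|| with ||v|| = 1
    if (i > 1 && abs(ev_new - ev) <= tol * ev_new) {
      ev <- ev_new
      break
    }
    ev <- ev_new
    v <- v_new
  }
  sqrt(ev)
}

#' Smallest lambda1 giving the all-zero solution
#'
#' For `lambda2 > 0` the zero matrix is optimal iff every entry of the
#' gradient at zero is dominated by the l1 weight:
#' `lambda1 >= max|2 A' Yf C'| / lambda2`. Useful to anchor tuning grids.
#'
#' @inheritParams sgl_objective
#' @param lambda2 Mix parameter (> 0).
#' @export
lambda_max <- function(Yf, A, C, lambda2 = 0.5) {
  if (lambda2 <= 0) stop("`lambda2` must be > 0 for a finite lambda_max")
  Av <- sensing_values(A)
  Cv <- as_C_matrix(C)
  g0 <- 2 * Matrix::crossprod(Av, Yf %*% t(Cv))
  max(abs(g0)) / lambda2
}

#' Decode an image stack by FISTA
#'
#' Solves the sparse-group-LASSO problem with the Fast Iterative
#' Shrinkage-Thresholding Algorithm: starting from `X = 0`, iterate
#' `x_{k+1} = prox(y_k - step * grad(y_k))` with Nesterov momentum
#' `t_{k+1} = (1 + sqrt(1 + 4 t_k^2)) / 2`,
#' `y_{k+1} = x_{k+1} + ((t_k - 1)/t_{k+1}) (x_{k+1} - x_k)`.
#' Stops at `max_iters` or when the relative objective change over 10
#' iterations drops below `rel_tol`.
#'
#' @param Yf Filtered, vectorized `Nl x F` matrix (see [bandpass_stack()] and
#'   [vectorize_stack()]).
#' @param A Sensing matrix.
#' @param C Codebook.
#' @param params A [solver_params()].
#' @param grid A [grid_spec()] for the output field; inferred from `A` when it
#'   is a `sensing_matrix`.
#' @param seed Seed forwarded to [estimate_step()] (FISTA itself is
#'   deterministic).
#' @return A `molecule_field` at stage `raw_solver`, with attributes
#'   `objective` (trace of evaluated objective values), `iterations`, and
#'   `step`.
#' @export
fista_decode <- function(Yf, A, C, params, grid = NULL, seed = 1L) {
  stopifnot(inherits(params, "solver_params"))
  if (is.null(grid)) {
    if (!inherits(A, "sensing_matrix")) {
      stop("supply `grid` when `A` is not a sensing_matrix")
    }
    grid <- A$grid
  }
  Av <- sensing_values(A)
  Cv <- as_C_matrix(C)
  if (nrow(Yf) != nrow(Av) || ncol(Yf) != ncol(Cv)) {
    stop("Yf dimensions must be Nl x F, conformable with A and C")
  }
  step <- params$step_size %||% estimate_step(A, C, seed)

  x <- matrix(0, ncol(Av), nrow(Cv))
  y <- x
  tk <- 1
  obj_prev <- sgl_objective(x, Yf, Av, Cv, params) # objective from X = 0
  obj_trace <- obj_prev
  iters <- 0L
  for (k in seq_len(params$max_iters)) {
    grad <- gradient_datafit(y, Yf, Av, Cv)
    x_new <- prox_sparse_group(y - step * grad, step,
                               params$lambda1, params$lambda2,
                               nonneg = params$nonneg)
    if (!all(is.finite(x_new))) {
      stop("solver diverged (non-finite iterate); try a smaller step size")
    }
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    y <- x_new + ((tk - 1) / t_new) * (x_new - x)
    x <- x_new
    tk <- t_new
    iters <- k
    if (k %% 10L == 0L || k == params$max_iters) {
      obj <- sgl_objective(x, Yf, Av, Cv, params)
      obj_trace <- c(obj_trace, obj)
      if (abs(obj_prev - obj) <= params$rel_tol * max(obj_prev, .Machine$double.eps)) {
        obj_prev <- obj
        break
      }
      obj_prev <- obj
    }
  }
  out <- molecule_field(x, grid, stage = "raw_solver")
  attr(out, "objective") <- obj_trace
  attr(out, "iterations") <- iters
  attr(out, "step") <- step
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
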