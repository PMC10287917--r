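#' Sweep one decoding parameter on a few FOVs
#'
#' Implements the selection heuristic for the regularization weight `lambda1`
#' and the hard threshold `t_x`: decode a small number of FOVs at each
#' candidate value (all other parameters fixed), adaptively filter, and pick
#' the candidate with the most post-filter calls. The pre-filter count is
#' recorded too: as `lambda1` decreases the pre-filter count rises
#' monotonically while blank calls inflate the rejection rate, so the
#' post-filter count can peak at an interior candidate — that crossover is
#' exactly what the sweep exploits. Ties pick the smaller candidate (the
#' sparser solution).
#'
#' @param fovs List of FOV inputs, passed one at a time to `decode_fn`.
#' @param decode_fn `function(fov, value)` running the full chain through
#'   adaptive filtering and returning a transcript tibble with
#'   `passed_filter` set.
#' @param candidates Numeric candidate values, sorted ascending.
#' @param which Which parameter is swept: `"lambda1"` or `"t_x"` (metadata
#'   only; `decode_fn` closes over everything else).
#' @return A `sweep_result`: tibble of `candidate`, `pre_filter_count`,
#'   `post_filter_count` plus a `chosen` attribute.
#' @export
sweep_parameter <- function(fovs, decode_fn, candidates,
                            which = c("lambda1", "t_x")) {
  which <- match.arg(which)
  if (length(candidates) == 0L) stop("`candidates` must be non-empty")
  if (is.unsorted(candidates, strictly = TRUE)) {
    stop("`candidates` must be sorted strictly ascending")
  }
  pre <- post <- numeric(length(candidates))
  for (i in seq_along(candidates)) {
    for (fov in fovs) {
      calls <- decode_fn(fov, candidates[i])
      pre[i] <- pre[i] + nrow(calls)
      post[i] <- post[i] + sum(calls$passed_filter == "kept")
    }
  }
  if (all(post == 0) && all(pre == 0)) {
    stop("no spots decoded at any candidate; widen the candidate grid")
  }
  chosen <- candidates[which.max(post)] # which.max takes the first (smallest)
  structure(
    tibble::tibble(
      parameter = which,
      candidate = as.numeric(candidates),
      pre_filter_count = pre,
      post_filter_count = post
    ),
    chosen = chosen,
    class = c("sweep_result", "tbl_df", "tbl", "data.frame")
  )
}

#' Chosen value of a parameter sweep
#' @param sweep A `sweep_result`.
#' @export
chosen_value <- function(sweep) attr(sweep, "chosen")

#' Default candidate grids for the sequential sweep
#'
#' `lambda1`: 8 log-spaced values spanning `[lambda_max/100, lambda_max]`
#' where `lambda_max` is the zero-solution bound from [lambda_max()].
#' `t_x`: 8 linear values between the 10% and 90% quantiles of the nonzero
#' recovered intensities.
#'
#' @param lmax Zero-solution bound for the FOVs being tuned.
#' @param n_candidates Grid size (default 8).
#' @export
lambda1_grid <- function(lmax, n_candidates = 8L) {
  exp(seq(log(lmax / 100), log(lmax), length.out = n_candidates))
}

#' @rdname lambda1_grid
#' @param x_nonzero Nonzero entries of a decoded field at the chosen
#'   `lambda1`.
#' @export
t_x_grid <- function(x_nonzero, n_candidates = 8L) {
  q <- stats::quantile(x_nonzero, c(0.1, 0.9), names = FALSE)
  g <- seq(q[1], q[2], length.out = n_candidates)
  unique(g)
}
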