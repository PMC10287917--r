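#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a decode result into its transcript calls
#'
#' @param x A `decode_result`.
#' @param ... Ignored.
#' @return The transcript tibble.
#' @method tidy decode_result
#' @export
tidy.decode_result <- function(x, ...) x$calls

#' One-row summary of a decode
#'
#' @param x A `decode_result`.
#' @param ... Ignored.
#' @return Tibble with per-stage counts, the final objective, iteration count
#'   and misidentification rate.
#' @method glance decode_result
#' @export
glance.decode_result <- function(x, ...) {
  r <- x$report
  tibble::tibble(
    fov = r$fov_id,
    z = r$z_index,
    lambda1 = r$lambda1,
    t_x = r$t_x,
    n_raw_nonzero = r$n_raw_nonzero,
    n_thresholded = r$n_thresholded,
    n_calls = r$n_calls,
    n_kept = r$n_kept,
    misidentification_rate = r$misidentification_rate,
    objective = r$objective[length(r$objective)],
    iterations = r$iterations
  )
}

#' Tidy a sweep result
#'
#' @param x A `sweep_result`.
#' @param ... Ignored.
#' @return The sweep tibble (candidate, pre/post-filter counts).
#' @method tidy sweep_result
#' @export
tidy.sweep_result <- function(x, ...) tibble::as_tibble(x)

#' One-row summary of a sweep
#' @param x A `sweep_result`.
#' @param ... Ignored.
#' @method glance sweep_result
#' @export
glance.sweep_result <- function(x, ...) {
  tibble::tibble(
    parameter = x$parameter[1],
    n_candidates = nrow(x),
    chosen = chosen_value(x),
    best_post_filter_count = max(x$post_filter_count)
  )
}

#' Tidy a fitted adaptive-filter model into its bins
#'
#' @param x A `filter_model`.
#' @param ... Ignored.
#' @return Tibble with one row per (intensity bin, area) cell: bin bounds,
#'   blank fraction and acceptance flag.
#' @method tidy filter_model
#' @export
tidy.filter_model <- function(x, ...) {
  nb <- x$n_intensity_bins
  bin <- seq_len(nb * x$n_area_bins)
  ib <- (bin - 1L) %% nb + 1L
  ia <- (bin - 1L) %/% nb + 1L
  tibble::tibble(
    bin = bin,
    log10_intensity_lo = x$intensity_edges[ib],
    log10_intensity_hi = x$intensity_edges[ib + 1L],
    area_bin = ia,
    blank_fraction = x$blank_fraction,
    accepted = x$accepted
  )
}

#' Tidy a match result into its matched pairs
#' @param x A `match_result`.
#' @param ... Ignored.
#' @method tidy match_result
#' @export
tidy.match_result <- function(x, ...) x$pairs

#' One-row precision/recall summary of a match
#' @param x A `match_result`.
#' @param ... Ignored.
#' @method glance match_result
#' @export
glance.match_result <- function(x, ...) {
  tibble::tibble(
    n_matched = nrow(x$pairs),
    precision = x$precision,
    recall = x$recall,
    match_radius = x$match_radius
  )
}
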