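#' Plot a parameter sweep
#'
#' Pre- and post-filter decoded spot counts against the candidate value, with
#' the chosen candidate marked. The divergence of the two curves at small
#' regularization is the blank-inflation effect the tuning heuristic exploits.
#'
#' @param object A `sweep_result`.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot sweep_result
#' @export
autoplot.sweep_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  long <- tidyr_pivot(df)
  ggplot2::ggplot(long, ggplot2::aes(.data$candidate, .data$count,
                                     colour = .data$stage)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = chosen_value(object), linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = df$parameter[1], y = "decoded spots", colour = NULL,
      title = sprintf("%s sweep (chosen %.4g)", df$parameter[1],
                      chosen_value(object))
    )
}

# minimal long-format reshape, avoids a tidyr dependency for one call
tidyr_pivot <- function(df) {
  dplyr::bind_rows(
    tibble::tibble(candidate = df$candidate, stage = "pre-filter",
                   count = df$pre_filter_count),
    tibble::tibble(candidate = df$candidate, stage = "post-filter",
                   count = df$post_filter_count)
  )
}

#' Plot transcript calls in FOV coordinates
#'
#' @param calls Transcript tibble.
#' @param colour_by Column mapped to colour (default `gene`).
#' @param kept_only Drop rejected calls first?
#' @return A ggplot (y axis flipped to image convention).
#' @export
plot_transcripts <- function(calls, colour_by = "gene", kept_only = FALSE) {
  if (kept_only) calls <- kept_calls(calls)
  ggplot2::ggplot(calls, ggplot2::aes(.data$col_highres, .data$row_highres,
                                      colour = .data[[colour_by]])) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (sub-pixels)", y = "y (sub-pixels)")
}

#' Plot the FISTA objective trace of a decode
#'
#' @param result A `decode_result`.
#' @return A ggplot of objective value against evaluation index.
#' @export
plot_objective <- function(result) {
  obj <- result$report$objective
  df <- tibble::tibble(evaluation = seq_along(obj) - 1, objective = obj)
  ggplot2::ggplot(df, ggplot2::aes(.data$evaluation, .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "objective evaluation (every 10 iterations)",
                  y = "objective")
}
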