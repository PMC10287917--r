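#' Blank-barcode misidentification rate
#'
#' A blank-normalized false-positive estimate: the mean number of calls per
#' blank barcode divided by the mean number of calls per coding barcode,
#' `(blank_calls / n_blank_barcodes) / (coding_calls / n_coding_barcodes)`.
#' Zero when no blank calls; 1 when blanks and coding genes are called at the
#' same per-barcode rate.
#'
#' @param calls Transcript tibble (uses `gene_index`).
#' @param codebook A [codebook()] with at least one blank and one coding
#'   barcode.
#' @return Scalar >= 0; `NaN` (with a warning) when there are no coding
#'   calls, where the rate is undefined.
#' @export
misidentification_rate <- function(calls, codebook) {
  n_blank_bc <- sum(codebook$is_blank)
  n_coding_bc <- sum(!codebook$is_blank)
  if (n_blank_bc == 0 || n_coding_bc == 0) {
    stop("codebook must contain at least one blank and one coding barcode")
  }
  blank <- codebook$is_blank[calls$gene_index]
  n_blank <- sum(blank)
  n_coding <- sum(!blank)
  if (n_blank == 0) return(0)
  if (n_coding == 0) {
    warning("no coding calls: misidentification rate undefined")
    return(NaN)
  }
  (n_blank / n_blank_bc) / (n_coding / n_coding_bc)
}

# assign calls to 2-D histogram bins: log10-intensity x capped integer area.
# Returns NA for calls outside the fitted intensity range.
filter_bin_of <- function(calls, model) {
  li <- log10(pmax(calls$intensity, .Machine$double.xmin))
  ib <- findInterval(li, model$intensity_edges, rightmost.closed = TRUE)
  ib[li < model$intensity_edges[1]] <- NA
  ib[li > model$intensity_edges[length(model$intensity_edges)]] <- NA
  ab <- pmin(calls$area, model$n_area_bins)
  ifelse(is.na(ib), NA_integer_, (ab - 1L) * model$n_intensity_bins + ib)
}

#' Fit the blank-driven adaptive filter
#'
#' Calls are binned on a 2-D histogram over (log10 intensity, area): 20
#' equal-width log-intensity bins by one bin per integer area up to
#' `n_area_bins`, larger areas pooled into the last bin (keeping the area
#' axis coarse enough that every populated bin carries a usable blank-call
#' count; with one bin per distinct area, sparsely populated bins of spurious
#' calls can contain no blanks by chance and escape rejection). Bins are
#' sorted by ascending blank-call fraction — estimated with a 5x5
#' bin-neighborhood pool, which stabilizes the estimate in sparsely populated
#' bins — and accepted greedily while the estimated misidentification rate of
#' the accepted set stays within `target_misid_rate`; low-quality bins
#' (blank-rich: dim and/or small calls) are dropped first. Empty bins carry
#' blank fraction 0 and are accepted (harmless by construction); bins
#' containing only blank calls are never accepted (known false positives
#' cannot improve the transcript yield). When the unfiltered calls already
#' meet the budget, every bin is accepted and the filter is a no-op.
#'
#' @param calls Transcript tibble from [extract_transcripts()]; must be
#'   non-empty.
#' @param codebook A [codebook()] with at least one blank barcode.
#' @param target_misid_rate Acceptance budget on the post-filter estimated
#'   misidentification rate (default 0.05).
#' @param n_intensity_bins Number of log10-intensity bins (default 20).
#' @param n_area_bins Number of area bins; areas `>= n_area_bins` share the
#'   last bin (default 10).
#' @return A `filter_model`.
#' @export
fit_filter <- function(calls, codebook, target_misid_rate = 0.05,
                       n_intensity_bins = 20L, n_area_bins = 10L) {
  if (nrow(calls) == 0L) stop("cannot fit a filter on an empty call table")
  if (sum(codebook$is_blank) == 0) {
    stop("codebook has no blank barcodes; skip adaptive filtering instead")
  }
  li <- log10(pmax(calls$intensity, .Machine$double.xmin))
  edges <- seq(min(li), max(li), length.out = n_intensity_bins + 1L)
  if (edges[1] == edges[length(edges)]) {
    edges <- edges + seq(-0.5, 0.5, length.out = length(edges))
  }
  n_bins <- n_intensity_bins * n_area_bins

  model <- structure(
    list(
      intensity_edges = edges,
      n_area_bins = as.integer(n_area_bins),
      n_intensity_bins = as.integer(n_intensity_bins),
      accepted = rep(TRUE, n_bins),
      blank_fraction = rep(0, n_bins),
      target_misid_rate = target_misid_rate,
      n_blank_bc = sum(codebook$is_blank),
      n_coding_bc = sum(!codebook$is_blank)
    ),
    class = "filter_model"
  )

  bin <- filter_bin_of(calls, model)
  blank <- codebook$is_blank[calls$gene_index]
  blank_per_bin <- vapply(seq_len(n_bins), function(b) sum(blank[bin == b], na.rm = TRUE), 0)
  coding_per_bin <- vapply(seq_len(n_bins), function(b) sum(!blank[bin == b], na.rm = TRUE), 0)
  total <- blank_per_bin + coding_per_bin
  model$blank_fraction <- ifelse(total > 0, blank_per_bin / total, 0)

  # blank fraction used for ORDERING is pooled over a 5x5 bin neighborhood:
  # a sparsely populated bin of spurious calls can contain zero blanks by
  # sampling accident, but its neighbors in feature space will not, so
  # neighborhood pooling sorts such bins after the clean signal bins instead
  # of in front of them
  smooth_fraction <- {
    nbm <- matrix(blank_per_bin, n_intensity_bins, n_area_bins)
    ntm <- matrix(total, n_intensity_bins, n_area_bins)
    pool <- function(M) {
      P <- matrix(0, nrow(M), ncol(M))
      for (di in -2:2) for (dj in -2:2) {
        si <- pmin(pmax(seq_len(nrow(M)) + di, 1L), nrow(M))
        sj <- pmin(pmax(seq_len(ncol(M)) + dj, 1L), ncol(M))
        P <- P + M[si, sj, drop = FALSE]
      }
      P
    }
    nb_s <- pool(nbm)
    nt_s <- pool(ntm)
    as.vector(ifelse(nt_s > 0, nb_s / nt_s, 0))
  }
  model$blank_fraction_smoothed <- smooth_fraction

  # if the unfiltered data already meets the budget there is nothing to
  # reject: accept every bin (the filter is a no-op)
  overall <- if (sum(coding_per_bin) > 0) {
    (sum(blank_per_bin) / model$n_blank_bc) /
      (sum(coding_per_bin) / model$n_coding_bc)
  } else {
    Inf
  }
  if (overall <= target_misid_rate) {
    model$accepted <- rep(TRUE, n_bins)
    return(model)
  }

  # greedy admission: best (lowest pooled blank fraction) bins first; stop
  # when the running misidentification rate of the accepted set would exceed
  # the budget, or at a bin that contributes only blank calls (keeping known
  # false positives can never improve the yield of real transcripts)
  ord <- order(smooth_fraction, model$blank_fraction, seq_len(n_bins))
  accepted <- rep(FALSE, n_bins)
  acc_blank <- 0
  acc_coding <- 0
  for (b in ord) {
    if (blank_per_bin[b] > 0 && coding_per_bin[b] == 0) next
    nb <- acc_blank + blank_per_bin[b]
    nc <- acc_coding + coding_per_bin[b]
    rate <- if (nc == 0) {
      if (nb == 0) 0 else Inf
    } else {
      (nb / model$n_blank_bc) / (nc / model$n_coding_bc)
    }
    if (rate <= target_misid_rate) {
      accepted[b] <- TRUE
      acc_blank <- nb
      acc_coding <- nc
    } else {
      break
    }
  }
  model$accepted <- accepted
  model
}

#' @export
print.filter_model <- function(x, ...) {
  cat(sprintf(
    "<filter_model> %d x %d bins, %d accepted, misid budget %.3g\n",
    x$n_intensity_bins, x$n_area_bins, sum(x$accepted),
    x$target_misid_rate
  ))
  invisible(x)
}

#' Apply a fitted adaptive filter
#'
#' Marks each call `"kept"` or `"rejected"` according to its bin; calls whose
#' features fall outside every fitted bin are rejected. Idempotent, and never
#' changes a call's gene, position or intensity.
#'
#' @param calls Transcript tibble.
#' @param model A `filter_model` from [fit_filter()].
#' @return The tibble with `passed_filter` set.
#' @export
apply_filter <- function(calls, model) {
  stopifnot(inherits(model, "filter_model"))
  bin <- filter_bin_of(calls, model)
  kept <- !is.na(bin) & model$accepted[ifelse(is.na(bin), 1L, bin)]
  dplyr::mutate(calls, passed_filter = ifelse(kept, "kept", "rejected"))
}

#' Kept calls of a filtered transcript table
#' @param calls Transcript tibble with `passed_filter` set.
#' @export
kept_calls <- function(calls) {
  dplyr::filter(calls, .data$passed_filter == "kept")
}

#' Serialize / restore a fitted filter model (JSON)
#'
#' A fitted model can be reused across FOVs; the JSON artifact is small and
#' human-readable.
#'
#' @param model A `filter_model`.
#' @param path JSON file path.
#' @export
write_filter_model <- function(model, path) {
  stopifnot(inherits(model, "filter_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_filter_model
#' @export
read_filter_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$n_intensity_bins <- as.integer(m$n_intensity_bins)
  m$n_area_bins <- as.integer(m$n_area_bins)
  structure(m, class = "filter_model")
}
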