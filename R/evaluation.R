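#' Cluster homogeneity score
#'
#' Measures how well gene-expression clusters respect spatial layer
#' membership: `h = 1 - H(layer | cluster) / H(layer)`, with entropies over
#' the cells' (cluster, layer) contingency table (natural logs; the base
#' cancels in the ratio, and `0 log 0 := 0`). The score lies in \[0, 1\]: 1
#' when every cluster contains cells of a single layer (a layer split across
#' several pure clusters still scores 1), 0 when clusters carry no layer
#' information. Invariant to relabeling of either side. When `H(layer) = 0`
#' (a single layer) the score is 1 by convention.
#'
#' @param clusters Per-cell cluster labels, or a contingency matrix
#'   (rows = clusters, columns = layers) if `layers` is missing.
#' @param layers Per-cell layer labels (same length as `clusters`).
#' @return Scalar in \[0, 1\].
#' @examples
#' homogeneity_score(c(1, 1, 2, 2), c("a", "a", "b", "b")) # pure: 1
#' homogeneity_score(c(1, 1, 1, 1), c("a", "a", "b", "b")) # uninformative: 0
#' @export
homogeneity_score <- function(clusters, layers) {
  tab <- if (missing(layers)) {
    as.matrix(clusters)
  } else {
    if (length(clusters) != length(layers)) {
      stop("`clusters` and `layers` must have the same length")
    }
    unclass(table(clusters, layers))
  }
  if (sum(tab) == 0) stop("empty contingency table")
  N <- sum(tab)
  p_layer <- colSums(tab) / N
  H_layer <- -sum(ifelse(p_layer > 0, p_layer * log(p_layer), 0))
  if (H_layer == 0) return(1)
  n_c <- rowSums(tab)
  P <- tab / N
  cond <- ifelse(tab > 0, P * log(tab / n_c[row(tab)]), 0)
  H_cond <- -sum(cond)
  1 - H_cond / H_layer
}

#' Match predicted transcript calls to ground truth
#'
#' Builds a one-to-one matching between predicted and true molecules of the
#' same gene within `match_radius` (Euclidean, sub-pixel units), greedily by
#' ascending distance. Precision is the matched fraction of predictions,
#' recall the matched fraction of truths; an empty prediction set scores
#' precision 1 (no false positives) and recall 0.
#'
#' @param predicted Transcript tibble (uses `gene_index` or `gene`,
#'   `row_highres`, `col_highres`).
#' @param truth Ground-truth molecule tibble with the same columns (or a
#'   `ground_truth` object).
#' @param match_radius Maximum match distance in sub-pixels (> 0).
#' @return A `match_result`: list with `pairs` (tibble of `pred`, `truth`,
#'   `distance`), `precision`, `recall`, `match_radius`.
#' @export
match_calls <- function(predicted, truth, match_radius = 1) {
  if (match_radius <= 0) stop("`match_radius` must be > 0")
  if (inherits(truth, "ground_truth")) truth <- truth$molecules
  gene_of <- function(df) {
    if ("gene_index" %in% names(df)) df$gene_index else df$gene
  }
  np <- nrow(predicted)
  nt <- nrow(truth)
  pairs <- tibble::tibble(pred = integer(), truth = integer(),
                          distance = numeric())
  if (np > 0 && nt > 0) {
    pg <- gene_of(predicted)
    tg <- gene_of(truth)
    cand <- list()
    for (g in intersect(unique(pg), unique(tg))) {
      pi <- which(pg == g)
      ti <- which(tg == g)
      d <- outer(predicted$row_highres[pi], truth$row_highres[ti], "-")^2 +
           outer(predicted$col_highres[pi], truth$col_highres[ti], "-")^2
      ok <- which(d <= match_radius^2, arr.ind = TRUE)
      if (nrow(ok) > 0) {
        cand[[length(cand) + 1L]] <- data.frame(
          pred = pi[ok[, 1]], truth = ti[ok[, 2]],
          distance = sqrt(d[ok])
        )
      }
    }
    if (length(cand) > 0) {
      cand <- do.call(rbind, cand)
      cand <- cand[order(cand$distance, cand$pred, cand$truth), ]
      used_p <- logical(np)
      used_t <- logical(nt)
      keep <- logical(nrow(cand))
      for (i in seq_len(nrow(cand))) {
        if (!used_p[cand$pred[i]] && !used_t[cand$truth[i]]) {
          keep[i] <- TRUE
          used_p[cand$pred[i]] <- TRUE
          used_t[cand$truth[i]] <- TRUE
        }
      }
      pairs <- tibble::as_tibble(cand[keep, ])
    }
  }
  structure(
    list(
      pairs = pairs,
      precision = if (np == 0) 1 else nrow(pairs) / np,
      recall = if (nt == 0) 1 else nrow(pairs) / nt,
      match_radius = match_radius
    ),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf(
    "<match_result> %d pairs (radius %.3g): precision %.3f, recall %.3f\n",
    nrow(x$pairs), x$match_radius, x$precision, x$recall
  ))
  invisible(x)
}

#' Pseudo-bulk expression correlation between two cell tables
#'
#' Sums each cell-by-gene table over cells, optionally log10-transforms with
#' a pseudocount, and returns the Pearson correlation of the two per-gene
#' vectors over the shared gene set.
#'
#' @param S1,S2 `cell_table` objects or bare cells-by-genes matrices with
#'   gene column names.
#' @param log_transform Apply `log10(x + pseudocount)` first?
#' @param pseudocount Pseudocount for the log transform.
#' @return Pearson correlation coefficient.
#' @export
pseudobulk_correlation <- function(S1, S2, log_transform = FALSE,
                                   pseudocount = 1) {
  mat_of <- function(S) if (inherits(S, "cell_table")) S$S else as.matrix(S)
  m1 <- mat_of(S1)
  m2 <- mat_of(S2)
  shared <- intersect(colnames(m1), colnames(m2))
  if (length(shared) < 2) stop("need at least 2 shared genes")
  v1 <- colSums(m1[, shared, drop = FALSE])
  v2 <- colSums(m2[, shared, drop = FALSE])
  if (log_transform) {
    v1 <- log10(v1 + pseudocount)
    v2 <- log10(v2 + pseudocount)
  }
  stats::cor(v1, v2)
}
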