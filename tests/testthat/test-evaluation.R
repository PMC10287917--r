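test_that("homogeneity score matches its analytic anchors", {
  # perfectly layer-pure clusters score exactly 1
  expect_identical(homogeneity_score(rbind(c(50, 0), c(0, 50))), 1)
  expect_identical(homogeneity_score(c(1, 1, 2, 2), c("a", "a", "b", "b")), 1)
  # a layer split across pure clusters still scores 1
  expect_identical(homogeneity_score(rbind(c(10, 0), c(20, 0), c(0, 30))), 1)
  # one cluster over two equally sized layers scores exactly 0
  expect_identical(homogeneity_score(rbind(c(25, 25))), 0)
  # single layer: score 1 by convention (H(layer) = 0)
  expect_identical(homogeneity_score(rbind(c(5), c(7))), 1)

  # mixed contingency table against the independent entropy computation
  tab <- rbind(c(5, 0), c(2, 3))
  expect_equal(homogeneity_score(tab), homogeneity_reference(tab),
               tolerance = 1e-12)

  expect_error(homogeneity_score(1:3, 1:4), "length")
})

test_that("homogeneity score agrees with the reference on random tables and is label-invariant", {
  set.seed(23)
  for (i in 1:20) {
    C <- sample(2:5, 1)
    K <- sample(2:4, 1)
    tab <- matrix(rpois(C * K, 4), C, K)
    if (sum(tab) == 0) tab[1, 1] <- 1
    h <- homogeneity_score(tab)
    expect_gte(h, 0)
    expect_lte(h, 1)
    expect_equal(h, homogeneity_reference(tab), tolerance = 1e-12)
    # invariance under row and column permutations
    expect_equal(homogeneity_score(tab[sample(C), sample(K), drop = FALSE]),
                 h, tolerance = 1e-12)
  }

  # merging two clusters with identical layer composition leaves h unchanged
  tab <- rbind(c(4, 2), c(8, 4), c(1, 9))
  merged <- rbind(c(12, 6), c(1, 9))
  expect_equal(homogeneity_score(merged), homogeneity_score(tab),
               tolerance = 1e-12)
})

test_that("call matching is one-to-one, gene-aware, and optimal on tiny instances", {
  truth <- tibble::tibble(
    gene_index = c(1L, 1L, 2L),
    row_highres = c(10, 20, 30),
    col_highres = c(10, 20, 30)
  )
  # predicted == truth
  m <- match_calls(truth, truth, match_radius = 1)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)

  # all displaced beyond the radius
  far <- dplyr::mutate(truth, row_highres = row_highres + 5)
  m2 <- match_calls(far, truth, match_radius = 1)
  expect_equal(m2$precision, 0)
  expect_equal(m2$recall, 0)

  # gene identity must match
  wrong_gene <- dplyr::mutate(truth, gene_index = c(2L, 2L, 1L))
  m3 <- match_calls(wrong_gene, truth, match_radius = 1)
  expect_equal(m3$precision, 0)

  # two predictions within radius of the same truth: exactly one match
  pred <- tibble::tibble(
    gene_index = c(1L, 1L),
    row_highres = c(10.2, 10.4),
    col_highres = c(10, 10)
  )
  m4 <- match_calls(pred, truth, match_radius = 1)
  expect_equal(nrow(m4$pairs), 1)
  expect_equal(m4$precision, 1 / 2)
  expect_equal(m4$recall, 1 / 3)

  # empty predictions: precision 1 by convention, recall 0
  m5 <- match_calls(truth[0, ], truth, match_radius = 1)
  expect_equal(m5$precision, 1)
  expect_equal(m5$recall, 0)

  expect_error(match_calls(truth, truth, match_radius = 0), "> 0")
})

test_that("greedy matching attains the optimal matching size on random tiny instances", {
  set.seed(31)
  for (i in 1:15) {
    np <- sample(1:5, 1)
    nt <- sample(1:5, 1)
    pred <- tibble::tibble(
      gene_index = sample(1:2, np, replace = TRUE),
      row_highres = runif(np, 0, 6),
      col_highres = runif(np, 0, 6)
    )
    truth <- tibble::tibble(
      gene_index = sample(1:2, nt, replace = TRUE),
      row_highres = runif(nt, 0, 6),
      col_highres = runif(nt, 0, 6)
    )
    r <- 2
    m <- match_calls(pred, truth, match_radius = r)
    adj <- outer(seq_len(np), seq_len(nt), Vectorize(function(p, t) {
      pred$gene_index[p] == truth$gene_index[t] &&
        (pred$row_highres[p] - truth$row_highres[t])^2 +
        (pred$col_highres[p] - truth$col_highres[t])^2 <= r^2
    }))
    opt <- brute_force_max_matching(matrix(adj, np, nt))
    # greedy nearest-first is a maximal matching: never exceeds the optimum
    # and attains at least half of it; pairs are strictly one-to-one
    expect_lte(nrow(m$pairs), opt)
    expect_gte(nrow(m$pairs), ceiling(opt / 2))
    expect_false(anyDuplicated(m$pairs$pred) > 0)
    expect_false(anyDuplicated(m$pairs$truth) > 0)
  }
})

test_that("precision and recall shrink (or stay) as the radius shrinks", {
  set.seed(37)
  pred <- tibble::tibble(
    gene_index = sample(1:3, 30, replace = TRUE),
    row_highres = runif(30, 0, 50),
    col_highres = runif(30, 0, 50)
  )
  truth <- tibble::tibble(
    gene_index = sample(1:3, 25, replace = TRUE),
    row_highres = runif(25, 0, 50),
    col_highres = runif(25, 0, 50)
  )
  radii <- c(8, 4, 2, 1, 0.5)
  ms <- lapply(radii, function(r) match_calls(pred, truth, r))
  prec <- vapply(ms, `[[`, 0, "precision")
  rec <- vapply(ms, `[[`, 0, "recall")
  expect_true(all(diff(prec) <= 0))
  expect_true(all(diff(rec) <= 0))
})

test_that("pseudo-bulk correlation follows the Pearson formula", {
  S1 <- matrix(c(1, 0, 2, 0, 1, 2, 0, 4, 0), 3, 3,
               dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(pseudobulk_correlation(S1, S1), 1)
  expect_equal(pseudobulk_correlation(S1, 2 * S1), 1) # scale invariance

  # 4-gene toy vectors (1,2,3,4) vs (2,4,6,9): hand-expanded Pearson
  S2 <- matrix(c(1, 2, 3, 4), 1, 4, dimnames = list(NULL, letters[1:4]))
  S3 <- matrix(c(2, 4, 6, 9), 1, 4, dimnames = list(NULL, letters[1:4]))
  x <- c(1, 2, 3, 4); y <- c(2, 4, 6, 9)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pseudobulk_correlation(S2, S3), r_hand)

  # log transform applies log10(x + pseudocount) before correlating
  lx <- log10(x + 1); ly <- log10(y + 1)
  r_log <- sum((lx - mean(lx)) * (ly - mean(ly))) /
    sqrt(sum((lx - mean(lx))^2) * sum((ly - mean(ly))^2))
  expect_equal(pseudobulk_correlation(S2, S3, log_transform = TRUE), r_log)

  # shared-gene intersection and the two-gene minimum
  S4 <- matrix(c(5, 1), 1, 2, dimnames = list(NULL, c("a", "zz")))
  expect_error(pseudobulk_correlation(S2, S4), "shared genes")
})
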