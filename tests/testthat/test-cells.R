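toy_mask <- function() {
  # 4x4 low-res mask with two 2x2 cells: cell 1 top-left, cell 3 bottom-right
  lab <- matrix(0L, 4, 4)
  lab[1:2, 1:2] <- 1L
  lab[3:4, 3:4] <- 3L
  segmentation_mask(lab, fov_id = 1L, fov_origin = c(10, 20))
}

toy_calls <- function(grid) {
  # 5 kept calls on the high-res (8x8, s = 2) grid:
  #  (0,0) and (3,2) -> cell 1; (5,5), (7,6) -> cell 3; (2,5) -> background
  tibble::tibble(
    fov = 1L, z = 0L,
    gene_index = c(1L, 2L, 1L, 1L, 2L),
    gene = c("g1", "g2", "g1", "g1", "g2"),
    row_highres = c(0, 3, 5, 7, 2),
    col_highres = c(0, 2, 5, 6, 5),
    row_px = c(0, 3, 5, 7, 2),
    col_px = c(0, 2, 5, 6, 5),
    area = 2L,
    intensity = c(10, 20, 30, 40, 50),
    passed_filter = "kept"
  )
}

test_that("cell area filter implements the median rule over all FOVs", {
  # areas (10, 10, 2): median 10, cell of area 2 < 5 is rejected
  lab <- matrix(0L, 6, 6)
  lab[1:2, 1:5] <- 1L
  lab[4:5, 1:5] <- 2L
  lab[6, 1:2] <- 3L
  m <- segmentation_mask(lab)
  out <- filter_cells_by_area(m)
  expect_setequal(setdiff(unique(as.vector(out$labels)), 0L), c(1L, 2L))

  # all-equal areas: nothing rejected
  lab2 <- matrix(0L, 4, 4)
  lab2[1:2, 1:2] <- 1L
  lab2[3:4, 3:4] <- 2L
  out2 <- filter_cells_by_area(segmentation_mask(lab2))
  expect_setequal(setdiff(unique(as.vector(out2$labels)), 0L), c(1L, 2L))

  # a single cell is its own median and never rejected
  lab3 <- matrix(0L, 3, 3)
  lab3[2, 2] <- 7L
  out3 <- filter_cells_by_area(segmentation_mask(lab3))
  expect_equal(sum(out3$labels == 7L), 1)

  # scale invariance: blowing the mask up leaves the partition unchanged
  big <- segmentation_mask(kronecker(lab, matrix(1L, 3, 3)))
  outb <- filter_cells_by_area(big)
  expect_setequal(setdiff(unique(as.vector(outb$labels)), 0L), c(1L, 2L))

  # multi-FOV median is shared: alone, a mask of two cells areas (4, 4) keeps
  # both; pooled with three cells of area 25 the median moves to 25 and the
  # small cells fall below half of it
  m_small <- segmentation_mask(lab2)
  lab_big <- matrix(0L, 17, 17)
  lab_big[1:5, 1:5] <- 1L
  lab_big[1:5, 7:11] <- 2L
  lab_big[7:11, 1:5] <- 3L
  both <- filter_cells_by_area(list(m_small, segmentation_mask(lab_big)))
  expect_equal(setdiff(unique(as.vector(both[[1]]$labels)), 0L), integer(0))
  expect_warning(filter_cells_by_area(segmentation_mask(matrix(0L, 2, 2))),
                 "no labeled cells")
})

test_that("transcripts are assigned to the cell under their rounded centroid", {
  grid <- grid_spec(4, 2, pixel_size = 0.5)
  mask <- toy_mask()
  calls <- toy_calls(grid)
  ids <- assign_transcripts(calls, mask, grid)
  expect_equal(as.integer(ids), c(1L, 1L, 3L, 3L, 0L))

  # rejected calls are never assigned
  calls$passed_filter[1] <- "rejected"
  ids2 <- assign_transcripts(calls, mask, grid)
  expect_equal(as.integer(ids2), c(0L, 1L, 3L, 3L, 0L))

  # centroid outside the mask extent counts as unassigned
  far <- calls[1, ]
  far$passed_filter <- "kept"
  far$row_px <- 100
  ids3 <- assign_transcripts(far, mask, grid)
  expect_equal(as.integer(ids3), 0L)
  expect_equal(attr(ids3, "n_outside_mask"), 1L)
})

test_that("cell table tallies counts and positions correctly", {
  grid <- grid_spec(4, 2, pixel_size = 0.5)
  mask <- toy_mask()
  cb <- tiny_codebook()
  calls <- toy_calls(grid)
  tab <- build_cell_table(calls, mask, cb, grid)

  # hand-tallied S: cell 1 has one g1 and one g2; cell 3 has two g1
  expect_equal(unname(tab$S), rbind(c(1L, 1L, 0L), c(2L, 0L, 0L)))
  # conservation: sum(S) equals the number of kept, in-cell calls
  expect_equal(sum(tab$S), 4)

  # positions: cell 1 centroid at pixel (0.5, 0.5) -> 0.25 um + origin
  expect_equal(tab$cells$cell_id, c(1L, 3L))
  expect_equal(tab$cells$xr_um, c(0.25, 1.25))
  expect_equal(tab$cells$yr_um, c(0.25, 1.25))
  expect_equal(tab$cells$x_um, c(10.25, 11.25))
  expect_equal(tab$cells$y_um, c(20.25, 21.25))
  expect_equal(tab$cells$area, c(4L, 4L))

  # no calls: counts all zero, rows preserved
  tab0 <- build_cell_table(calls[0, ], mask, cb, grid)
  expect_equal(sum(tab0$S), 0)
  expect_equal(nrow(tab0$S), 2)
})

test_that("FOV-edge correction equalizes per-bin means to the global mean", {
  # hand-built two-bin table: gene means 2 and 4, global mean 3
  S <- matrix(c(2, 2, 4, 4), 4, 1, dimnames = list(NULL, "g1"))
  cells <- tibble::tibble(
    cell_id = 1:4, fov = 0L, z = 0L, area = 10L,
    x_um = 0, y_um = 0, z_um = 0, xr_um = 0, yr_um = 0, zr_um = 0,
    dist_to_center_px = c(1, 1, 9, 9)
  )
  tab <- structure(list(S = S, cells = cells, gene_names = "g1"),
                   class = "cell_table")
  out <- fov_edge_correction(tab, K = 2)
  ec <- attr(out, "edge_correction")
  expect_equal(as.vector(ec$scale), c(1.5, 0.75))
  expect_equal(as.vector(out$S), c(3, 3, 3, 3))

  # radius-independent expression: all scales 1, S unchanged
  S2 <- matrix(3, 4, 1, dimnames = list(NULL, "g1"))
  tab2 <- structure(list(S = S2, cells = cells, gene_names = "g1"),
                    class = "cell_table")
  out2 <- fov_edge_correction(tab2, K = 2)
  expect_equal(out2$S, S2)

  # a gene absent from one bin keeps scale 1 there
  S3 <- matrix(c(0, 0, 4, 4), 4, 1, dimnames = list(NULL, "g1"))
  tab3 <- structure(list(S = S3, cells = cells, gene_names = "g1"),
                    class = "cell_table")
  out3 <- fov_edge_correction(tab3, K = 2)
  expect_equal(attr(out3, "edge_correction")$scale[1, 1], 1)
  expect_equal(as.vector(out3$S)[1:2], c(0, 0))

  expect_error(fov_edge_correction(tab, K = 0), ">= 1")
})

test_that("per-bin means equal the global mean after correction on random tables", {
  set.seed(14)
  for (rep in 1:3) {
    Nc <- 40
    G <- 5
    S <- matrix(rpois(Nc * G, 6), Nc, G,
                dimnames = list(NULL, paste0("g", 1:G)))
    cells <- tibble::tibble(
      cell_id = seq_len(Nc), fov = 0L, z = 0L, area = 10L,
      x_um = 0, y_um = 0, z_um = 0, xr_um = 0, yr_um = 0, zr_um = 0,
      dist_to_center_px = runif(Nc, 0, 20)
    )
    tab <- structure(list(S = S, cells = cells,
                          gene_names = colnames(S)),
                     class = "cell_table")
    K <- 4
    out <- fov_edge_correction(tab, K = K)
    bin <- attr(out, "edge_correction")$bin
    gm <- colMeans(S)
    for (k in unique(bin)) {
      mk <- colMeans(out$S[bin == k, , drop = FALSE])
      nz <- colMeans(S[bin == k, , drop = FALSE]) > 0
      expect_equal(mk[nz], gm[nz], tolerance = 1e-9)
    }
  }
})

test_that("masks round-trip through TIFF", {
  lab <- matrix(0L, 6, 6)
  lab[2:3, 2:3] <- 5L
  lab[5, 5] <- 300L # forces 16-bit
  m <- segmentation_mask(lab, fov_id = 2L)
  f <- withr::local_tempfile(fileext = ".tif")
  write_mask(m, f)
  m2 <- read_mask(f, fov_id = 2L)
  expect_equal(m2$labels, m$labels)
})
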