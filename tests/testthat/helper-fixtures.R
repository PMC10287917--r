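# Shared fixture builders. Everything is generated in code at test time; the
# expensive default-scene sensing matrix is built once per test run and
# cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- build()
  .fixture_cache[[key]]
}

tiny_grid <- function(n = 4L, s = 1L) grid_spec(n, s, pixel_size = 0.1)

tiny_codebook <- function() {
  codebook(
    c("g1", "g2", "Blank-1"),
    rbind(c(1, 1, 0, 0),
          c(0, 1, 1, 0),
          c(0, 0, 1, 1)),
    is_blank = c(FALSE, FALSE, TRUE)
  )
}

random_instance <- function(seed, n = 6L, s = 1L, G = 4L, F = 5L) {
  set.seed(seed)
  grid <- grid_spec(n, s, pixel_size = 0.1)
  A <- build_sensing_matrix(grid, psf_sigma = stats::runif(1, 0.4, 0.9))
  C <- matrix(stats::rbinom(G * F, 1, 0.4), G, F)
  # avoid all-zero / duplicate rows
  C[rowSums(C) == 0, 1] <- 1
  Yf <- matrix(stats::rnorm(grid$Nl * F), grid$Nl, F)
  list(grid = grid, A = A, C = C, Yf = Yf, G = G, F = F)
}

# the default synthetic study scene: n = 64, s = 3, F = 16, G = 16 + 4
# blanks, 50 molecules at >= 6 sub-pixels separation
scene_grid <- function() cached("scene_grid", function() grid_spec(64L, 3L))

scene_codebook <- function() {
  cached("scene_codebook", function() {
    generate_codebook(G = 16L, F = 16L, weight = 4L, min_hamming = 4L,
                      n_blanks = 4L, seed = 7L)
  })
}

scene_sensing <- function() {
  cached("scene_sensing", function() {
    build_sensing_matrix(scene_grid(), psf_sigma = 1.0)
  })
}

scene_truth <- function(seed = 11L) {
  sample_ground_truth(scene_grid(), scene_codebook(), n_molecules = 50L,
                      min_separation = 6, seed = seed)
}

# per-spot SNR ~ 5 for the default scene: the PSF places ~16% of a
# molecule's intensity in its peak pixel, so a median-intensity (1000)
# molecule peaks at ~160 counts, and 160 / (2.5 * sqrt(160 + 1)) ~ 5
scene_noise <- function() {
  noise_params(background_amplitude = 100, shot_noise_scale = 2.5,
               bit_brightness_jitter = 0.05)
}

# a small, fast end-to-end scene for io/pipeline tests
small_scene <- function(seed = 5L, noise = noise_params()) {
  grid <- cached("small_grid", function() grid_spec(32L, 2L))
  cb <- cached("small_codebook", function() {
    generate_codebook(G = 6L, F = 8L, weight = 3L, min_hamming = 2L,
                      n_blanks = 2L, seed = 3L)
  })
  A <- cached("small_sensing", function() {
    build_sensing_matrix(grid_spec(32L, 2L), psf_sigma = 0.8)
  })
  truth <- sample_ground_truth(grid, cb, n_molecules = 12L,
                               min_separation = 6, seed = seed)
  stack <- render_stack(truth, A, noise, seed = seed + 1L)
  list(grid = grid, codebook = cb, A = A, truth = truth, stack = stack)
}

small_config <- function(lambda1, t_x) {
  cfg <- default_config()
  cfg$grid$n <- 32L
  cfg$grid$s <- 2L
  cfg$psf$sigma <- 0.8
  cfg$solver$lambda1 <- lambda1
  cfg$spots$t_x <- t_x
  cfg
}

# synthetic transcript calls with prescribed blank/coding intensity overlap
synthetic_calls <- function(n_coding, n_blank, codebook, seed = 1L,
                            coding_intensity = c(500, 1500),
                            blank_intensity = c(5, 50),
                            area_range = c(4L, 12L)) {
  set.seed(seed)
  coding_idx <- which(!codebook$is_blank)
  blank_idx <- which(codebook$is_blank)
  gi <- c(sample(coding_idx, n_coding, replace = TRUE),
          sample(blank_idx, n_blank, replace = TRUE))
  n <- n_coding + n_blank
  intensity <- c(stats::runif(n_coding, coding_intensity[1], coding_intensity[2]),
                 stats::runif(n_blank, blank_intensity[1], blank_intensity[2]))
  tibble::tibble(
    fov = 0L, z = 0L,
    gene_index = gi,
    gene = codebook$gene_names[gi],
    row_highres = stats::runif(n, 0, 100),
    col_highres = stats::runif(n, 0, 100),
    row_px = 0, col_px = 0,
    area = sample(seq(area_range[1], area_range[2]), n, replace = TRUE),
    intensity = intensity,
    passed_filter = "unfiltered"
  )
}
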