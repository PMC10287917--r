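#' Generate a constant-weight codebook with minimum Hamming distance
#'
#' Rejection-samples F-bit codewords of constant weight until `G + n_blanks`
#' codewords with pairwise Hamming distance at least `min_hamming` are found.
#' Blank barcodes are drawn from the same code (so they are as decodable as
#' real genes) and named `Blank-<k>`. Deterministic for a given seed. The
#' MERFISH-like regime is `F = 16`, weight 4, distance 4 (an MHD4 code).
#'
#' @param G Number of coding genes.
#' @param F Barcode length (imaging rounds).
#' @param weight Number of 1-bits per codeword.
#' @param min_hamming Minimum pairwise Hamming distance (0 disables the
#'   constraint beyond distinctness).
#' @param n_blanks Number of blank barcodes.
#' @param seed RNG seed.
#' @param max_attempts Sampling attempts before giving up (the request may be
#'   infeasible).
#' @return A [codebook()].
#' @export
generate_codebook <- function(G = 16L, F = 16L, weight = 4L, min_hamming = 4L,
                              n_blanks = 4L, seed = 1L,
                              max_attempts = 20000L) {
  total <- G + n_blanks
  if (total > choose(F, weight)) {
    stop(sprintf("requested %d codewords but only %d of weight %d exist",
                 total, choose(F, weight), weight))
  }
  set.seed(seed)
  codes <- matrix(0, 0, F)
  attempts <- 0L
  while (nrow(codes) < total) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop("could not find a feasible codebook; relax weight/min_hamming")
    }
    cand <- numeric(F)
    cand[sample.int(F, weight)] <- 1
    if (nrow(codes) > 0) {
      dists <- rowSums(abs(sweep(codes, 2, cand)))
      if (any(dists < max(min_hamming, 1L))) next
    }
    codes <- rbind(codes, cand)
  }
  names_ <- c(sprintf("Gene-%02d", seq_len(G)),
              if (n_blanks > 0) sprintf("Blank-%d", seq_len(n_blanks)))
  codebook(names_, codes,
           is_blank = c(rep(FALSE, G), rep(TRUE, n_blanks)))
}

#' Synthetic imaging noise parameters
#'
#' Emulates the two dominant noise sources in fluorescence iST images: a
#' low-frequency autofluorescence background that varies smoothly across the
#' FOV (white noise convolved with a wide Gaussian, sigma = n/4 pixels, scaled
#' to `background_amplitude`), and high-frequency shot noise, modeled by
#' default as Gaussian with variance proportional to signal plus a floor
#' (`sd = shot_noise_scale * sqrt(signal + shot_noise_floor)`), which keeps
#' the generator continuous and seed-stable; a Poisson switch is available.
#' A per-bit multiplicative brightness jitter emulates round-to-round
#' illumination variation.
#'
#' @param background_amplitude Peak amplitude of the background field
#'   (intensity units; 0 disables).
#' @param background_sigma Smoothing sigma of the background field in low-res
#'   pixels, or `NULL` for the default n/4.
#' @param shot_noise_scale Scale of the signal-dependent noise sd (0
#'   disables).
#' @param shot_noise_floor Variance floor (intensity units).
#' @param bit_brightness_jitter Relative sd of the per-bit brightness factor
#'   (0 disables).
#' @param model `"gaussian"` (default) or `"poisson"`.
#' @export
noise_params <- function(background_amplitude = 0, background_sigma = NULL,
                         shot_noise_scale = 0, shot_noise_floor = 1,
                         bit_brightness_jitter = 0,
                         model = c("gaussian", "poisson")) {
  vals <- c(background_amplitude, shot_noise_scale, shot_noise_floor,
            bit_brightness_jitter)
  if (any(vals < 0)) stop("noise parameters must be >= 0")
  structure(
    list(
      background_amplitude = background_amplitude,
      background_sigma = background_sigma,
      shot_noise_scale = shot_noise_scale,
      shot_noise_floor = shot_noise_floor,
      bit_brightness_jitter = bit_brightness_jitter,
      model = match.arg(model)
    ),
    class = "noise_params"
  )
}

#' Sample a ground-truth molecule configuration
#'
#' Places `n_molecules` molecules uniformly on the sub-pixel grid subject to a
#' minimum pairwise (Euclidean, sub-pixel units) separation, assigns genes
#' uniformly over the non-blank codebook rows (or per a supplied abundance
#' vector), and draws intensities from a log-normal. Blank barcodes are never
#' generated, so every downstream blank call is a false positive by
#' construction.
#'
#' @param grid A [grid_spec()].
#' @param codebook A [codebook()].
#' @param n_molecules Number of molecules.
#' @param intensity_meanlog,intensity_sdlog Log-normal intensity parameters
#'   (defaults give a median intensity of 1000 with ~25% spread).
#' @param min_separation Minimum pairwise distance in sub-pixels (0 disables).
#' @param gene_probs Optional abundance vector over non-blank genes.
#' @param seed RNG seed.
#' @param max_attempts Placement retries before giving up.
#' @return A `ground_truth`: tibble `molecules` (`gene_index`, `gene`,
#'   `row_highres`, `col_highres`, `intensity`) plus the grid, codebook and
#'   seed.
#' @export
sample_ground_truth <- function(grid, codebook, n_molecules = 50L,
                                intensity_meanlog = log(1000),
                                intensity_sdlog = 0.25,
                                min_separation = 6,
                                gene_probs = NULL, seed = 1L,
                                max_attempts = 10000L) {
  if (n_molecules > grid$Nh) stop("more molecules than sub-pixel sites")
  set.seed(seed)
  N <- grid$n * grid$s
  rows <- numeric(0)
  cols <- numeric(0)
  attempts <- 0L
  while (length(rows) < n_molecules) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop("could not place molecules at the requested separation")
    }
    r <- sample.int(N, 1L) - 1L
    c <- sample.int(N, 1L) - 1L
    if (min_separation > 0 && length(rows) > 0) {
      if (min(sqrt((rows - r)^2 + (cols - c)^2)) < min_separation) next
    }
    rows <- c(rows, r)
    cols <- c(cols, c)
  }
  coding <- which(!codebook$is_blank)
  genes <- if (n_molecules == 0) integer(0)
           else coding[sample.int(length(coding), n_molecules, replace = TRUE,
                                  prob = gene_probs)]
  intens <- stats::rlnorm(n_molecules, intensity_meanlog, intensity_sdlog)
  structure(
    list(
      molecules = tibble::tibble(
        gene_index = genes,
        gene = codebook$gene_names[genes],
        row_highres = rows,
        col_highres = cols,
        intensity = intens
      ),
      grid = grid,
      codebook = codebook,
      seed = seed
    ),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d molecules on a %dx%d sub-pixel grid\n",
              nrow(x$molecules), x$grid$n * x$grid$s, x$grid$n * x$grid$s))
  invisible(x)
}

#' Molecule field X of a ground truth
#'
#' @param truth A `ground_truth`.
#' @return Sparse `Nh x G` matrix with one nonzero per molecule.
#' @export
truth_field <- function(truth) {
  N <- truth$grid$n * truth$grid$s
  mol <- truth$molecules
  Matrix::sparseMatrix(
    i = rc_to_index(mol$row_highres, mol$col_highres, N),
    j = mol$gene_index,
    x = mol$intensity,
    dims = c(truth$grid$Nh, n_genes(truth$codebook))
  )
}

# smooth nonnegative background field in [0, amplitude], seeded by caller
background_field <- function(n, sigma, amplitude) {
  raw <- matrix(stats::rnorm(n * n), n, n)
  d <- seq_len(n) - 1
  K1 <- exp(-outer(d, d, function(a, b) (a - b)^2) / (2 * sigma^2))
  sm <- K1 %*% raw %*% K1
  sm <- sm - min(sm)
  if (max(sm) > 0) sm <- sm / max(sm)
  sm * amplitude
}

#' Render a synthetic image stack from a ground truth
#'
#' Computes the noiseless stack `A X C`, then per image adds the smooth
#' background field, applies the per-bit brightness jitter, and adds shot
#' noise. All randomness derives from `seed`; with all noise parameters zero
#' the output is exactly the noiseless model.
#'
#' @param truth A `ground_truth` from [sample_ground_truth()].
#' @param A A `sensing_matrix` on the same grid.
#' @param noise A [noise_params()].
#' @param seed RNG seed for the noise draws.
#' @param fov_id,z_index Provenance for the output stack.
#' @return A raw `image_stack` of `F` images.
#' @export
render_stack <- function(truth, A, noise = noise_params(), seed = 1L,
                         fov_id = 0L, z_index = 0L) {
  stopifnot(inherits(truth, "ground_truth"), inherits(noise, "noise_params"))
  grid <- truth$grid
  X <- truth_field(truth)
  Y0 <- forward_model(X, A, truth$codebook)
  n <- grid$n
  F <- n_bits(truth$codebook)
  set.seed(seed)
  jitter <- if (noise$bit_brightness_jitter > 0) {
    stats::rnorm(F, 1, noise$bit_brightness_jitter)
  } else {
    rep(1, F)
  }
  bg_sigma <- noise$background_sigma %||% (n / 4)
  images <- vector("list", F)
  for (f in seq_len(F)) {
    im <- matrix(Y0[, f], n, n, byrow = TRUE)
    if (noise$background_amplitude > 0) {
      im <- im + background_field(n, bg_sigma, noise$background_amplitude)
    }
    im <- im * jitter[f]
    if (noise$model == "poisson") {
      sc <- max(noise$shot_noise_scale, .Machine$double.eps)
      im <- matrix(stats::rpois(n * n, pmax(im, 0) / sc^2) * sc^2, n, n)
    } else if (noise$shot_noise_scale > 0) {
      sd <- noise$shot_noise_scale *
        sqrt(pmax(im, 0) + noise$shot_noise_floor)
      # camera counts are nonnegative: clamp the Gaussian tail at zero
      im <- pmax(im + matrix(stats::rnorm(n * n, 0, 1), n, n) * sd, 0)
    }
    images[[f]] <- im
  }
  image_stack(images, fov_id = fov_id, z_index = z_index, is_filtered = FALSE)
}

#' Write / read a ground truth as CSV
#'
#' Columns: `gene,row_highres,col_highres,intensity`.
#' @param truth A `ground_truth`.
#' @param path CSV path.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.csv(
    data.frame(
      gene = truth$molecules$gene,
      row_highres = truth$molecules$row_highres,
      col_highres = truth$molecules$col_highres,
      intensity = format(truth$molecules$intensity, digits = 17)
    ),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname write_ground_truth
#' @param grid,codebook Context objects to reattach on read.
#' @export
read_ground_truth <- function(path, grid, codebook) {
  df <- utils::read.csv(path, colClasses = c(gene = "character"))
  gi <- match(df$gene, codebook$gene_names)
  if (anyNA(gi)) stop("ground-truth CSV names genes absent from the codebook")
  structure(
    list(
      molecules = tibble::tibble(
        gene_index = gi,
        gene = df$gene,
        row_highres = df$row_highres,
        col_highres = df$col_highres,
        intensity = as.numeric(df$intensity)
      ),
      grid = grid,
      codebook = codebook,
      seed = NA_integer_
    ),
    class = "ground_truth"
  )
}
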