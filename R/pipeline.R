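#' Default pipeline configuration
#'
#' A nested list mirroring the module parameters, serializable to YAML via
#' [write_config()] / [read_config()]. Every parameter has a default except
#' `solver.lambda1` and `spots.t_x`, which must come from [tune_decode()] or
#' be set explicitly before [run_decode()] will run.
#'
#' @return Named list of sections `grid`, `denoise`, `solver`, `spots`,
#'   `filter`, `cells`, `tuning`, `seed`.
#' @export
default_config <- function() {
  list(
    grid = list(n = 64L, s = 3L, pixel_size = 0.167, z_spacing = 1.5),
    psf = list(sigma = 1.0, truncation_sigmas = 3.0),
    denoise = list(sigma_narrow = 0.75, sigma_broad = 3.0, kernel_radius = 9L),
    solver = list(lambda1 = NULL, lambda2 = 0.5, max_iters = 200L,
                  rel_tol = 1e-6, nonneg = FALSE),
    spots = list(t_x = NULL, min_cluster_size = 2L, connectivity = 8L),
    filter = list(target_misid_rate = 0.05, n_intensity_bins = 20L,
                  n_area_bins = 10L),
    cells = list(edge_bins = 10L),
    tuning = list(n_fovs = 3L, n_candidates = 8L),
    seed = 1L
  )
}

#' Read / write a pipeline configuration (YAML)
#'
#' Unknown keys are rejected; missing keys take their defaults. The
#' round-trip `read_config(write_config(cfg))` is lossless.
#'
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_config(default_config(), user)
}

#' @rdname read_config
#' @param config Configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

merge_config <- function(base, user) {
  for (k in names(user)) {
    if (!k %in% names(base)) stop(sprintf("unknown config key `%s`", k))
    if (is.list(base[[k]])) {
      for (k2 in names(user[[k]])) {
        if (!k2 %in% names(base[[k]])) {
          stop(sprintf("unknown config key `%s.%s`", k, k2))
        }
        base[[k]][[k2]] <- user[[k]][[k2]]
      }
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

config_grid <- function(config) {
  do.call(grid_spec, config$grid)
}

#' Decode one field of view end to end
#'
#' Runs the full chain on a raw image stack: band-pass denoise, FISTA solve,
#' row one-sparsification, hard threshold, connected-component transcript
#' extraction, and blank-driven adaptive filtering. Deterministic: the same
#' config, inputs and seed give byte-identical transcript tables.
#'
#' @param stack Raw `image_stack` (F must match the codebook).
#' @param codebook A [codebook()].
#' @param A `sensing_matrix`; built from the config's `psf` section when
#'   `NULL` (pass a prebuilt one when decoding many FOVs).
#' @param config Configuration list from [default_config()] /
#'   [read_config()], with `solver.lambda1` and `spots.t_x` set.
#' @param filter_model Optional prefit `filter_model` to reuse across FOVs;
#'   when `NULL` one is fit on this FOV's calls (skipped with a warning if
#'   the codebook has no blanks or no calls survive thresholding).
#' @return A `decode_result`: list with `calls` (transcript tibble with
#'   `passed_filter` set), `field` (thresholded `molecule_field`),
#'   `filter_model`, and `report` (per-stage counts, objective trace,
#'   misidentification rate, timings).
#' @export
run_decode <- function(stack, codebook, A = NULL, config = default_config(),
                       filter_model = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  if (length(stack$images) != n_bits(codebook)) {
    stop(sprintf("stack has %d images but the codebook has %d bits",
                 length(stack$images), n_bits(codebook)))
  }
  if (is.null(config$solver$lambda1) || is.null(config$spots$t_x)) {
    stop("config must set solver.lambda1 and spots.t_x (run tune_decode() or set them explicitly)")
  }
  grid <- config_grid(config)
  if (grid$n != stack$n) stop("config grid n does not match the stack")
  if (is.null(A)) {
    A <- build_sensing_matrix(grid, config$psf$sigma,
                              config$psf$truncation_sigmas * config$psf$sigma)
  }
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  bp <- bandpass_params(config$denoise$sigma_narrow,
                        config$denoise$sigma_broad,
                        config$denoise$kernel_radius)
  Yf <- vectorize_stack(bandpass_stack(stack, bp))
  timings["denoise"] <- tic() - t0

  t0 <- tic()
  sp <- solver_params(config$solver$lambda1, config$solver$lambda2,
                      config$solver$max_iters, config$solver$rel_tol,
                      nonneg = isTRUE(config$solver$nonneg))
  X <- fista_decode(Yf, A, codebook, sp, seed = config$seed)
  timings["solve"] <- tic() - t0

  t0 <- tic()
  X1 <- row_one_sparsify(X)
  Xt <- hard_threshold(X1, config$spots$t_x)
  spp <- spot_params(config$spots$t_x, config$spots$min_cluster_size,
                     config$spots$connectivity)
  calls <- extract_transcripts(Xt, spp, codebook,
                               fov_id = stack$fov_id, z_index = stack$z_index)
  timings["spots"] <- tic() - t0

  t0 <- tic()
  if (is.null(filter_model)) {
    if (nrow(calls) > 0 && any(codebook$is_blank)) {
      filter_model <- fit_filter(calls, codebook,
                                 config$filter$target_misid_rate,
                                 config$filter$n_intensity_bins,
                                 config$filter$n_area_bins)
    } else if (!any(codebook$is_blank)) {
      warning("codebook has no blank barcodes; skipping adaptive filtering")
    }
  }
  calls <- if (!is.null(filter_model)) {
    apply_filter(calls, filter_model)
  } else {
    dplyr::mutate(calls, passed_filter = "kept")
  }
  timings["filter"] <- tic() - t0

  kept <- sum(calls$passed_filter == "kept")
  misid <- if (any(codebook$is_blank) && kept > 0) {
    misidentification_rate(kept_calls(calls), codebook)
  } else {
    NA_real_
  }
  structure(
    list(
      calls = calls,
      field = Xt,
      filter_model = filter_model,
      report = list(
        fov_id = stack$fov_id,
        z_index = stack$z_index,
        lambda1 = config$solver$lambda1,
        t_x = config$spots$t_x,
        n_raw_nonzero = Matrix::nnzero(field_values(X1)),
        n_thresholded = Matrix::nnzero(field_values(Xt)),
        n_calls = nrow(calls),
        n_kept = kept,
        misidentification_rate = misid,
        objective = attr(X, "objective"),
        iterations = attr(X, "iterations"),
        timings = timings
      )
    ),
    class = "decode_result"
  )
}

#' @export
print.decode_result <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "<decode_result> fov %s z %d: %d calls, %d kept (misid rate %s), %d FISTA iters\n",
    format(r$fov_id), r$z_index, r$n_calls, r$n_kept,
    ifelse(is.na(r$misidentification_rate), "NA",
           sprintf("%.3g", r$misidentification_rate)),
    r$iterations
  ))
  invisible(x)
}

#' Tune lambda1 and t_x by the post-filter spot-count heuristic
#'
#' Sequential sweeps on a few FOVs: first `lambda1` over a log grid spanning
#' `[lambda_max/100, lambda_max]`, then (holding the chosen `lambda1`) `t_x`
#' over linear quantiles of the recovered nonzero intensities. Each candidate
#' is decoded through adaptive filtering and the candidate maximizing the
#' kept-call count is chosen. FISTA solutions are cached per `lambda1`, so
#' the `t_x` sweep reuses the chosen solve.
#'
#' @param stacks List of raw `image_stack`s (a small number of FOVs).
#' @param codebook A [codebook()].
#' @param A Prebuilt `sensing_matrix` (or `NULL` to build from config).
#' @param config Configuration (its `lambda1`/`t_x` entries are ignored).
#' @param lambda1_candidates,t_x_candidates Optional explicit grids.
#' @return List with `lambda1`, `t_x`, the two `sweep_result`s, and `config`
#'   updated with the chosen values.
#' @export
tune_decode <- function(stacks, codebook, A = NULL, config = default_config(),
                        lambda1_candidates = NULL, t_x_candidates = NULL) {
  if (inherits(stacks, "image_stack")) stacks <- list(stacks)
  grid <- config_grid(config)
  if (is.null(A)) {
    A <- build_sensing_matrix(grid, config$psf$sigma,
                              config$psf$truncation_sigmas * config$psf$sigma)
  }
  bp <- bandpass_params(config$denoise$sigma_narrow,
                        config$denoise$sigma_broad,
                        config$denoise$kernel_radius)
  Yfs <- lapply(stacks, function(s) vectorize_stack(bandpass_stack(s, bp)))

  if (is.null(lambda1_candidates)) {
    lmax <- max(vapply(Yfs, lambda_max, 0, A = A, C = codebook,
                       lambda2 = config$solver$lambda2))
    lambda1_candidates <- lambda1_grid(lmax, config$tuning$n_candidates)
  }

  solve_cache <- new.env(parent = emptyenv())
  solve_at <- function(i, l1) {
    key <- sprintf("%d_%.17g", i, l1)
    if (is.null(solve_cache[[key]])) {
      sp <- solver_params(l1, config$solver$lambda2, config$solver$max_iters,
                          config$solver$rel_tol,
                          nonneg = isTRUE(config$solver$nonneg))
      X <- fista_decode(Yfs[[i]], A, codebook, sp, seed = config$seed)
      solve_cache[[key]] <- row_one_sparsify(X)
    }
    solve_cache[[key]]
  }
  call_at <- function(i, l1, t_x) {
    Xt <- hard_threshold(solve_at(i, l1), t_x)
    spp <- spot_params(t_x, config$spots$min_cluster_size,
                       config$spots$connectivity)
    calls <- extract_transcripts(Xt, spp, codebook,
                                 fov_id = stacks[[i]]$fov_id,
                                 z_index = stacks[[i]]$z_index)
    if (nrow(calls) == 0 || !any(codebook$is_blank)) {
      return(dplyr::mutate(calls, passed_filter = "kept"))
    }
    fm <- fit_filter(calls, codebook, config$filter$target_misid_rate,
                     config$filter$n_intensity_bins,
                     config$filter$n_area_bins)
    apply_filter(calls, fm)
  }

  # t_x placeholder during the lambda1 sweep: keep everything positive
  sweep1 <- sweep_parameter(
    seq_along(stacks),
    function(i, l1) call_at(i, l1, .Machine$double.xmin),
    lambda1_candidates, which = "lambda1"
  )
  l1 <- chosen_value(sweep1)

  if (is.null(t_x_candidates)) {
    xs <- unlist(lapply(seq_along(stacks), function(i) {
      field_values(solve_at(i, l1))@x
    }))
    xs <- xs[xs > 0]
    if (length(xs) == 0) stop("no positive recovered intensities at the chosen lambda1")
    t_x_candidates <- t_x_grid(xs, config$tuning$n_candidates)
  }
  sweep2 <- sweep_parameter(
    seq_along(stacks),
    function(i, t_x) call_at(i, l1, t_x),
    t_x_candidates, which = "t_x"
  )
  t_x <- chosen_value(sweep2)

  config$solver$lambda1 <- l1
  config$spots$t_x <- t_x
  list(lambda1 = l1, t_x = t_x,
       lambda1_sweep = sweep1, t_x_sweep = sweep2,
       config = config)
}

#' Write / read a transcript call table (CSV)
#'
#' One row per call with both sub-pixel (0-based) and micrometre coordinates:
#' `fov,z,gene,x_highres,y_highres,x_um,y_um,area,intensity,passed_filter`.
#' `x` is the column axis and `y` the row axis; `*_um = subpixel *
#' pixel_size / s + fov_origin`.
#'
#' @param calls Transcript tibble.
#' @param path CSV path.
#' @param grid A [grid_spec()] for the um conversion.
#' @param fov_origin FOV offset in um.
#' @export
write_transcripts <- function(calls, path, grid, fov_origin = c(0, 0)) {
  subpx <- grid$pixel_size / grid$s
  df <- data.frame(
    fov = calls$fov,
    z = calls$z,
    gene = calls$gene,
    x_highres = format_full(calls$col_highres),
    y_highres = format_full(calls$row_highres),
    x_um = format_full(calls$col_highres * subpx + fov_origin[1]),
    y_um = format_full(calls$row_highres * subpx + fov_origin[2]),
    area = calls$area,
    intensity = format_full(calls$intensity),
    passed_filter = calls$passed_filter
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

format_full <- function(x) vapply(x, format, "", digits = 17)

#' @rdname write_transcripts
#' @param codebook A [codebook()] to recover gene indices.
#' @export
read_transcripts <- function(path, grid, codebook) {
  df <- utils::read.csv(path, colClasses = c(gene = "character",
                                             passed_filter = "character"))
  subpx <- grid$pixel_size / grid$s
  gi <- match(df$gene, codebook$gene_names)
  if (anyNA(gi)) stop("transcript CSV names genes absent from the codebook")
  tibble::tibble(
    fov = df$fov,
    z = as.integer(df$z),
    gene_index = gi,
    gene = df$gene,
    row_highres = df$y_highres,
    col_highres = df$x_highres,
    row_px = round_half_up(df$y_highres),
    col_px = round_half_up(df$x_highres),
    area = as.integer(df$area),
    intensity = df$intensity,
    passed_filter = df$passed_filter
  )
}

#' Write a cell table as CSV + MatrixMarket
#'
#' Writes `<prefix>_counts.mtx` (sparse MatrixMarket), `<prefix>_cells.csv`
#' (cell metadata including absolute `x_um,y_um,z_um` and FOV-relative
#' `xr_um,yr_um,zr_um` positions) and `<prefix>_genes.csv` (column sidecar).
#'
#' @param table A `cell_table`.
#' @param prefix Output path prefix.
#' @export
write_cell_table <- function(table, prefix) {
  Matrix::writeMM(methods::as(Matrix::Matrix(table$S, sparse = TRUE),
                              "generalMatrix"),
                  paste0(prefix, "_counts.mtx"))
  cells <- table$cells
  cells$x_um <- format_full(cells$x_um)
  cells$y_um <- format_full(cells$y_um)
  cells$xr_um <- format_full(cells$xr_um)
  cells$yr_um <- format_full(cells$yr_um)
  cells$dist_to_center_px <- format_full(cells$dist_to_center_px)
  utils::write.csv(cells, paste0(prefix, "_cells.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(gene = table$gene_names),
                   paste0(prefix, "_genes.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(prefix)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(prefix) {
  S <- as.matrix(Matrix::readMM(paste0(prefix, "_counts.mtx")))
  cells <- tibble::as_tibble(
    utils::read.csv(paste0(prefix, "_cells.csv"))
  )
  genes <- utils::read.csv(paste0(prefix, "_genes.csv"),
                           colClasses = "character")$gene
  dimnames(S) <- list(cells$cell_id, genes)
  structure(
    list(S = S, cells = cells, gene_names = genes),
    class = "cell_table"
  )
}
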