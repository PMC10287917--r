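# istdecode

Optimization-based decoding of combinatorially barcoded imaging spatial
transcriptomics (iST) data — MERFISH and kin — in R.

## The problem

iST assays read out a targeted panel of G genes over F rounds of
fluorescence imaging: each gene carries an F-bit binary barcode from a known
codebook, and a single mRNA molecule lights up exactly in the rounds where
its barcode has a 1. Classic pipelines detect spots per round and then match
bit patterns, which needs well-separated optical signals and hence
high-magnification imaging. `istdecode` instead poses decoding as a sparse
recovery problem over the whole field of view (FOV): with the F images
vectorized into `Y ∈ R^(Nl×F)`, the data are modeled as

    Y = A X C + η

where `A` is the point-spread-function operator onto a sub-pixel grid
(`Nh = s²·Nl` sites, scale factor `s = 3` by default), `C` is the codebook
and `X ∈ R^(Nh×G)` is the unknown molecule field. `X` is recovered by
minimizing the sparse-group-LASSO objective

    ‖Y_f − A X C‖_F² + λ₁(1−λ₂) Σᵢ ‖X_{i,·}‖₂ + λ₁λ₂ ‖X‖₁

with FISTA (`Y_f` is the band-pass-filtered data). Decoded fields are
converted to discrete transcript calls (one-sparsification, hard threshold
`t_x`, connected components, centroids), filtered adaptively using the
blank barcodes so the estimated misidentification rate stays within budget,
assigned to segmented cells to build a cell-by-gene count matrix with
FOV-edge correction, and evaluated with precision/recall matching,
pseudo-bulk correlation, and the cluster homogeneity score
`h = 1 − H(layer|cluster)/H(layer)`.

A synthetic-data module generates ground-truth-annotated scenes from the
same generative model (codebook sampling, PSF blur, autofluorescence
background, shot noise), so the entire pipeline is testable without a
microscope.

## Worked example

Simulate one noisy FOV (64×64 px, s = 3, 16-bit MHD4 codebook with 4
blanks, 50 molecules at per-spot SNR ≈ 5), tune `λ₁`/`t_x` by the
post-filter spot-count heuristic, decode, and compare to ground truth:

```r
library(istdecode)

grid  <- grid_spec(n = 64, s = 3)
cb    <- generate_codebook(G = 16, F = 16, weight = 4, min_hamming = 4,
                           n_blanks = 4, seed = 7)
A     <- build_sensing_matrix(grid, psf_sigma = 1.0)
truth <- sample_ground_truth(grid, cb, n_molecules = 50,
                             min_separation = 6, seed = 11)
noise <- noise_params(background_amplitude = 100, shot_noise_scale = 2.5,
                      bit_brightness_jitter = 0.05)
stack <- render_stack(truth, A, noise, seed = 3)

cfg   <- default_config()
tuned <- tune_decode(list(stack), cb, A, cfg)
res   <- run_decode(stack, cb, A, tuned$config)
res
#> <decode_result> fov 0 z 0: 312 calls, 53 kept (misid rate 0), 200 FISTA iters

match_calls(kept_calls(res$calls), truth, match_radius = 1)
#> <match_result> 48 pairs (radius 1): precision 0.906, recall 0.960
```

Reading the numbers: the solver field thresholds down to 312 raw calls, the
blank-driven filter keeps 53 of them at an estimated misidentification rate
of 0 (no blank barcode survives), and 48 of the kept calls sit within one
sub-pixel of a true molecule of the same gene — 91% precision, 96% recall
at SNR ≈ 5. On the same scene with noise turned off the pipeline is exact
(precision = recall = 1).

`tidy()` / `glance()` return the calls and a one-row summary as tibbles;
`autoplot(tuned$lambda1_sweep)` shows the pre- vs post-filter count
crossover that the tuning heuristic exploits; `plot_transcripts(res$calls)`
maps the calls.

A command-line surface (`simulate`, `decode`, `tune`, `cells`, `evaluate`,
`show-config`) is installed at `exec/istdecode`:

```sh
ISTD=$(Rscript -e 'cat(file.path(find.package("istdecode"), "exec", "istdecode"))')
Rscript $ISTD simulate --out-dir sim --seed 2
Rscript $ISTD tune --codebook sim/codebook.csv --stack sim/stack.tif --out-dir tuned
Rscript $ISTD decode --config tuned/tuned_config.yaml --codebook sim/codebook.csv \
        --stack sim/stack.tif --out-dir dec
```

## Documentation

The methods vignette (`vignettes/decoding-model.Rmd`) documents the model,
every tunable parameter with its default and rationale, the numerical
choices (vectorization convention, PSF sampling, kernel normalization,
boundary handling, stopping rules, tie-breaks), what the synthetic generator
does and does not emulate, and known limitations.
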