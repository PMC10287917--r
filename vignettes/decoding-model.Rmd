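---
title: "Joint sparse decoding of imaging spatial transcriptomics data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint sparse decoding of imaging spatial transcriptomics data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(istdecode)
```

## The decoding problem

Combinatorially barcoded imaging spatial transcriptomics (iST) assays such as
MERFISH read out a panel of G genes over F rounds of fluorescence imaging.
Each gene carries an F-bit binary barcode; an individual mRNA molecule
appears as a diffraction-limited spot in exactly the rounds where its barcode
has a 1. A field of view (FOV) therefore yields F co-registered `n x n`
images, and decoding means recovering, from those images, where the
molecules are and which gene each one is.

`istdecode` treats this as a single linear inverse problem instead of the
classic spot-detect-then-match pipeline. Vectorizing and concatenating the F
images into `Y` (`Nl x F`, `Nl = n^2`), the data are modeled as

    Y = A X C + eta

* `X` (`Nh x G`) is the unknown molecule field on a sub-pixel grid: each
  camera pixel is split into `s^2` sub-pixels (`Nh = s^2 Nl`), and a nonzero
  entry `X[i, g]` is the intensity of a molecule of gene `g` at sub-pixel
  `i`. The super-resolution factor `s` defaults to 3: finer grids cost
  roughly `s^2` in compute and memory while the PSF limits how much extra
  localization they buy.
* `A` (`Nl x Nh`) encodes the microscope point-spread function: entry
  `(il, ih)` is the fraction of photons emitted at sub-pixel `ih` that
  lands in camera pixel `il`.
* `C` (`G x F`) is the known codebook, including "blank" rows — barcodes
  assigned to no gene, so that any call decoded to one is a known false
  positive.
* `eta` collects noise: a low-frequency autofluorescence background that
  varies smoothly across the FOV, and high-frequency uncorrelated shot
  noise.

Solving for `X` jointly performs deconvolution and barcode assignment, which
is what lets the method work at lower magnification, where spots overlap and
per-spot detection degrades.

## Module walk-through and the choices behind it

### Geometry and the sensing matrix

All images are vectorized **row-major** (row index varies slowest); a single
convention is used everywhere and round-trips exactly
(`vectorize_stack()` / `devectorize_stack()`). Low-res pixel `(r, c)` owns
sub-pixel rows `s*r .. s*r+s-1` and the center of sub-pixel index `i` sits at
`(i + 0.5)/s - 0.5` in pixel coordinates.

`build_sensing_matrix()` composes an isotropic Gaussian PSF, point-sampled
at sub-pixel center offsets, with `s x s` block-sum downsampling. Point
sampling (rather than integrating the PSF over pixel extents) is an
approximation; at `s = 3` with PSF sigma around one pixel the difference is
far below the noise floor, and an empirically measured `A` can be loaded
from the coordinate-triplet text format instead
(`read_sensing_matrix()`). The kernel is truncated at `3 * psf_sigma`
(Euclidean) and renormalized so that interior columns sum to exactly 1;
columns near the image border keep their truncated sums — photons leaving
the FOV are lost, as on a physical camera. `A` is sparse by construction and
only matrix products and column sums are ever needed.

### Band-pass prefilter

Each image is convolved with a difference-of-Gaussians kernel
(`dog_kernel()`): a narrow Gaussian (sigma 0.75 px) minus a broad one
(sigma 3 px), the printed parameters for 60x data; for other magnifications
both sigmas scale with the magnification ratio. Two numerical choices:

* each sampled Gaussian is renormalized to unit sum over the truncated
  support (radius `ceiling(3 * sigma_broad)` = 9 px by default). This makes
  the kernel sum exactly zero, so a constant background is removed exactly;
  the analytic (unnormalized) kernel would leak about 0.5% of the image mean
  through the truncation tail of the broad Gaussian. The cost is a ~4e-4
  relative shift from the analytic density values.
* convolution uses **reflect padding**. Zero padding would darken edges and
  bias spot intensities near borders, feeding systematic errors into the
  edge-correction step downstream.

Negative filtered values are retained going into the solver; the hard
threshold removes them later. Filtering must happen exactly once — the
`is_filtered` flag makes double application an error.

### The solver

`fista_decode()` minimizes

    || Yf - A X C ||_F^2
      + lambda1 * (1 - lambda2) * sum_i ||X[i, ]||_2
      + lambda1 * lambda2 * ||X||_1

the sparse-group-LASSO compromise between row sparsity (few occupied
locations — the group term) and overall sparsity (the l1 term), mixed by
`lambda2 = 0.5` by default. The one-molecule-per-location constraint is
*not* in the objective; it is imposed afterwards by `row_one_sparsify()`,
which works better in practice than constraining the solve.

FISTA implementation decisions:

* initialization at `X = 0`; deterministic fixed step `1/L` with
  `L = 2 sigma_max(A)^2 sigma_max(C)^2` estimated by power iteration
  (`estimate_step()`; the power-iteration start vector is the solver's only
  seeded randomness). No backtracking — a fixed step keeps runs bit
  reproducible.
* stopping: `max_iters` (default 200) plus a relative objective-change
  tolerance of 1e-6, evaluated every 10 iterations to limit cost. FISTA with
  momentum is not per-step monotone, so convergence is judged on the sampled
  trend.
* the iterates are unconstrained in sign, matching the objective; a
  `nonneg = TRUE` switch projects onto `X >= 0` inside the prox for users
  who want it. Negative entries are removed by the hard threshold anyway.
* each z-plane is decoded as an independent 2-D problem; nothing couples
  the z-stack (3-D decoding is a known extension, not attempted here).

`lambda_max()` gives the smallest `lambda1` with an all-zero solution
(`max|2 A' Yf C'| / lambda2`), the natural upper anchor for tuning grids.

### From solver field to transcript calls

The spot chain is staged (`raw_solver -> one_sparse -> thresholded ->
binarized`) and the stages are enforced, so mis-ordering is an error rather
than a silent bug:

1. `row_one_sparsify()`: keep each row's maximum (ties: lowest gene index,
   for determinism).
2. `hard_threshold()`: zero entries strictly below `t_x`; a value exactly at
   the threshold survives.
3. `extract_transcripts()`: per gene, connected components
   (8-connectivity by default, configurable to 4) of the nonzero sub-pixel
   image become calls; components smaller than `min_cluster_size` (default
   2 px — single-pixel components are mostly noise) are dropped. The call
   location is the **unweighted** centroid of member pixels, rounded
   half-up per axis; the continuous centroid, pixel area and the summed
   pre-binarization intensity are all retained, because the adaptive filter
   needs them.

### Blank-driven adaptive filtering

False positives are controlled with the blank barcodes. Calls are binned on
(log10 intensity, area) — 20 equal-width intensity bins by 10 area bins
(one per integer area, larger areas pooled) — and bins are admitted greedily
in order of increasing blank-call fraction while the estimated
misidentification rate of the admitted set,

    (blank calls / blank barcodes) / (coding calls / coding barcodes)

stays within the budget (`target_misid_rate`, default 0.05; the value is a
package default exposed in config, chosen as the conventional 5% level).
Two estimation details matter at moderate call counts:

* the ordering uses blank fractions pooled over a 5x5 bin neighborhood.
  With raw per-bin fractions, a sparsely populated bin of spurious calls can
  contain zero blanks by sampling accident and would sort ahead of genuine
  signal bins; pooling borrows strength from neighboring bins, whose blank
  content reveals the local false-positive density. On the package's noisy
  reference scene this is the difference between keeping ~150 spurious
  calls and keeping ~5.
* bins containing only blank calls are never admitted (they cannot add real
  transcripts), and if the unfiltered call set already meets the budget the
  filter is a no-op.

The fitted model is a small JSON artifact (`write_filter_model()`) so one
fit can be applied across FOVs. Filtering only ever flips the
`passed_filter` flag; positions, genes and intensities are untouched.

### Parameter tuning

`lambda1` and `t_x` are chosen by decoding a few FOVs over a candidate grid
and maximizing the **post-filter** call count (`tune_decode()`,
`sweep_parameter()`). The rationale: lowering `lambda1` increases raw calls
but inflates blank-rate-driven rejection, so the post-filter count peaks at
an interior value while the pre-filter count is monotone — both counts are
recorded so this crossover is visible (`autoplot()` on a sweep shows it).
The two parameters are tuned sequentially (`lambda1` first), never on a 2-D
grid; the FISTA solution is cached per `lambda1`, so the `t_x` sweep costs
no additional solves. Default grids: 8 log-spaced `lambda1` candidates on
`[lambda_max/100, lambda_max]`, then 8 linear `t_x` candidates between the
10% and 90% quantiles of the recovered nonzero intensities.

### Cells and the count matrix

Segmentation is an input (an integer label mask per FOV/z), not something
this package computes. Cells with area below half or above twice the median
(median taken across all FOVs before any rejection) are discarded. Kept
calls are assigned to the cell whose mask pixel contains their rounded
centroid; the cell-by-gene matrix `S`, absolute positions `L` and
FOV-relative positions `Lr` come out of `build_cell_table()`, with exact
count conservation (`sum(S)` equals the number of kept in-cell calls).

`fov_edge_correction()` compensates the radial expression bias caused by
objective aberrations: cells are binned by distance to the FOV center into
`K = 10` equal-width radial bins and each gene's counts are scaled by
`global mean / bin mean`. The scale is the ratio to the global mean — the
only reading that actually equalizes center and edge expression; after
correction every gene's per-bin mean equals its global mean by construction
(empty bins and zero-expression bins keep scale 1). Corrected counts are
real-valued.

### Evaluation

* `homogeneity_score()`: `1 - H(layer | cluster) / H(layer)` over a
  cell-level contingency table, natural logs (the base cancels),
  `0 log 0 := 0`, and 1 by convention when there is a single layer. Used to
  ask whether expression clusters respect spatial layers; 1 means every
  cluster is layer-pure.
* `match_calls()`: gene-aware one-to-one matching of predicted to true
  molecules, greedy by ascending distance within a radius. Greedy matching
  is deterministic and near-optimal at realistic densities; the test suite
  bounds it against exhaustive optimal matching on small instances.
  Precision and recall follow from the matching; an empty prediction set
  has precision 1 by convention.
* `pseudobulk_correlation()`: Pearson correlation of per-gene totals, with
  an optional `log10(x + 1)` transform.

## The synthetic data generator

`generate_codebook()` rejection-samples constant-weight codewords at a
minimum pairwise Hamming distance (the MERFISH-like default is 16 bits,
weight 4, distance 4), drawing blank barcodes from the same code so they are
statistically exchangeable with gene barcodes. `sample_ground_truth()`
places molecules uniformly at a minimum separation with log-normal
intensities, and `render_stack()` pushes the truth through `A X C` and adds:

* a smooth background field (white noise convolved with a Gaussian of sigma
  `n/4`, scaled to `background_amplitude`) — emulating autofluorescence that
  varies across the FOV;
* Gaussian shot noise with variance proportional to signal plus a floor,
  clamped at zero (camera counts are nonnegative). Gaussian-with-
  signal-variance is used instead of Poisson to keep the generator
  continuous and seed-stable; a Poisson switch exists;
* a per-bit multiplicative brightness jitter for round-to-round
  illumination variation.

Blank barcodes are never rendered, so every downstream blank call is a
ground-truth false positive — exactly the property the adaptive filter is
built on.

The default test scene is one FOV at `n = 64`, `s = 3`, `F = 16`,
`G = 16 + 4` blanks and 50 molecules separated by at least 6 sub-pixels —
large enough to exercise every stage, small enough to decode in seconds.
The noisy variant uses `background_amplitude = 100`,
`shot_noise_scale = 2.5` and 5% bit jitter, which puts the per-spot SNR near
5 (the PSF concentrates ~16% of a molecule's intensity in its peak pixel, so
a median molecule peaks at ~160 counts against noise sd
`2.5 * sqrt(161) ~ 32`).

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: optical aberrations and defocus (the PSF is
a single isotropic Gaussian), chromatic or field-dependent PSF variation,
imperfect registration across rounds, hybridization chemistry artifacts,
molecule clustering inside cells, and z-coupling between planes. Results on
the synthetic scenes validate the algorithmic chain, not instrument
physics.

## Reference problem sizes

The test suite and the worked examples run at desk scale, chosen so the
full suite completes in a few minutes: solver cross-checks against a
long-run proximal-gradient reference use instances up to `Nl = 64`,
`Nh = 144`, `G, F <= 8`; end-to-end scenes use the `n = 64, s = 3` FOV
above, with a `n = 32, s = 2` variant for IO and determinism checks.

## Known limitations

* The adaptive filter estimates rejection regions from one FOV's calls when
  no prefit model is supplied; with very few calls the histogram is coarse.
  Fitting once on pooled FOVs and applying everywhere
  (`filter_model` argument of `run_decode()`) is the intended production
  path.
* Greedy call matching can differ from the optimal assignment in
  pathological geometries (it is guaranteed within a factor 2 of the
  maximum matching size; in practice, at the call densities of the scenes
  here, it attains it).
* No registration, no 3-D decoding, no learned unrolling; each z-plane and
  FOV is independent.
* `misidentification_rate()` is undefined with zero coding calls and
  returns `NaN` with a warning rather than 0 — downstream code should treat
  that as "no evidence", not "clean".
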