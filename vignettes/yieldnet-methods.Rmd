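---
title: "Dual-head convolutional yield prediction from pixel histograms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-head convolutional yield prediction from pixel histograms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette explains the models implemented by **yieldnet**, the
assumptions behind them, the numerical choices made where the design was
genuinely open, and what the synthetic data generator does and does not
emulate. It states no empirical result that the package's test suite or
acceptance script does not itself compute.

## The problem

County-level corn and soybean yields (bushels/acre) are to be predicted
from multispectral satellite composite time series: per county-year,
`T = 30` eight-day composites over the March–October growing season, each
with `d = 9` bands (7 surface-reflectance bands plus day and night land
surface temperature), restricted to cropland pixels by an annual cropland
mask. Predictions are wanted *during* the season — on the 23rd of July,
August, September, and October — using only composites acquired by the
forecast date.

## Histogram reduction

End-to-end training on raw county rasters is impractical: labeled
county-years number in the low tens of thousands, counties vary in size
and shape, and multispectral imagery cannot reuse pretrained natural-image
backbones. The pipeline therefore adopts a permutation-invariance
assumption — average yield depends on the *composition* of pixel values
over cropland, not on where pixels sit — and reduces each composite to a
per-band histogram. Band values are discretized into `b = 32` bins, giving
a `b x d` matrix per composite and a `T x b x d` tensor per county-year.

Choices the histogram layer makes explicit:

* **Bin placement.** Per-band linear spacing between the minimum and
  maximum over valid pixels of *training-year* frames only, so bin edges
  never leak information from test years. Fixed sensor-valid ranges can be
  supplied instead (`compute_bin_edges(strategy = "fixed")`).
* **Normalization.** Frequencies per (time, band) — each histogram column
  sums to 1 — so counties of different areas are comparable. Raw counts
  remain available behind `normalization = "count"`.
* **Bin convention.** Half-open bins `[lo, hi)` with the last bin closed;
  out-of-range values clamp into the edge bins so pixel mass is conserved
  rather than silently dropped.
* **Missing composites** (e.g. fully cloud-void periods) become all-zero
  slices with a warning — the same encoding the in-season truncation uses,
  so the network sees one consistent "no data yet" representation.
* **Masking.** A single cropland mask per county-year (the union of the
  crops' cropland) feeds one histogram tensor mapped to both yields,
  matching the paired dataset definition `(H, (Y_corn, Y_soy))`.
* **Calendar.** Standard 8-day windows starting at day-of-year
  `1 + 8(n-1)`; retaining windows 9–38 (start days 65–297) gives exactly
  30 composites. Under this calendar the four forecast dates retain 18,
  22, 26, and 29 composites respectively.

In-season forecasting zeroes all slices whose composite *start* day
exceeds the forecast date (`truncate_season()`); one model is trained per
forecast date on identically truncated inputs, which keeps the network's
input shape fixed. Retraining per date was chosen over zero-filling at
inference only because it matches the fixed-shape architecture and lets
every date's model adapt its weights to the information actually
available.

## The dual-head network

Convolution is 2-D over (time, bin) with the 9 bands as input channels:
sliding over time captures temporal development, sliding over bins
captures shifts in the pixel-value distribution, and cross-channel mixing
captures spectral structure.

| Block | Layers |
|---|---|
| Shared backbone | Conv 7x7/s2 valid, 48 -> Conv 5x5/s2 valid, 64 -> Conv 5x5/s2 same, 96 -> Conv 3x3/s1 same, 128 -> Conv 3x3/s1 same, 128 |
| Each crop head | Conv 3x3/s1 same, 148 -> Conv 3x3/s1 same, 148 -> flatten -> FC-100 -> FC-50 -> linear 1 |

Every convolution is followed by batch normalization and ReLU; the FC
layers of the heads use ReLU without batch norm; the output is linear.
The five backbone layers are shared by both crop heads — the package's
transfer-learning mechanism — which is why the dual model's 1,436,050
parameters are far fewer than two single-crop networks (2 x 973,529).

Counting conventions (all forced by reproducing the published dual-model
total exactly, and verified in the test suite):

* a 1-unit linear output layer closes each head;
* batch norm contributes two trainable parameters per channel (scale and
  shift); running statistics are not parameters;
* convolution biases are retained even under batch norm;
* valid padding uses `floor((size - filter)/stride) + 1`, same padding
  `ceil(size/stride)` (the familiar TensorFlow rules), giving the
  backbone map (30, 32) -> (12, 13) -> (4, 5) -> (2, 3) and the head
  flatten width 2 * 3 * 148 = 888;
* no batch norm on the heads' fully connected layers.

The printed parameter totals of the two baseline networks could not be
reconciled with any straightforward counting convention, so they are
documented as this package counts them (`count_parameters(dfnn_spec())`,
`count_parameters(cnn3d_spec())`) and not treated as oracles.

## The normalized max-loss

With corn around 147 bu/acre and soybean around 45, plain summed squared
errors would let corn dominate. Each crop's mean squared residual is
normalized by the square of that crop's average yield,

\[
L = \max\!\left(
\frac{1}{N_c}\sum_i \Big(\frac{Y_i^c - \hat Y_i^c}{\bar Y^c}\Big)^2,\;
\frac{1}{N_s}\sum_i \Big(\frac{Y_i^s - \hat Y_i^s}{\bar Y^s}\Big)^2
\right),
\]

and the *maximum* of the two terms is minimized, so the optimizer always
works on whichever crop is currently worse and neither is neglected.
Decisions around the loss:

* \(\bar Y^c, \bar Y^s\) are fixed global training-set means supplied via
  `loss_config()`, not per-batch means, which would jitter the scaling at
  batch size 32.
* A batch carrying only one crop's labels contributes that crop's term
  alone (the maximum over an empty set is undefined).
* The max is subdifferentiated along the attained term, ties broken
  toward corn — frameworks differ here, so the choice is explicit.

## Training

Adam with learning rate 0.0005, mini-batches of 32 sampled with
replacement over location-years, 4000 iterations, Xavier-uniform weight
initialization, no dropout (batch normalization already regularizes), and
no early stopping. Batches are not stratified by crop: the loss simply
uses whichever labels are present, the simplest faithful reading of the
separate \(N_c, N_s\) in the loss.

Two engineering choices of this implementation:

* **Output-bias initialization.** Each head's output bias starts at the
  crop's training-mean yield, so optimization begins at the
  climatological prediction and spends its budget learning deviations
  rather than the ~147 bu/acre offset. This matters at small iteration
  budgets and is harmless at large ones.
* **Batch-norm constants.** Variance epsilon 1e-3 and running-statistic
  momentum 0.9; inference always uses running statistics, which makes
  prediction deterministic.

The engine itself is written in vectorised R over BLAS matrix products
(im2col convolution with precomputed gather indices, channel-major
activations) with one compiled kernel for the in-place Adam update. Every
layer's gradient is checked against central finite differences in the
test suite; the analytic/numeric relative error is required to be below
1e-5.

### Reduced-scale experiment sizes

The package's experiment protocol is exercised in tests and in the
acceptance script at reduced scale, chosen once as: histogram bins
`b = 16` (the architecture is unchanged, only the bin axis shrinks),
grids of 16 x 16 pixels, a few hundred training location-years, and
shortened Adam schedules (a few hundred iterations at the default
learning rate and batch size) with tail averaging over the final 30% of
iterates. Raising the learning rate instead of shortening gently was
tried and rejected: it destabilizes the dual-head model
disproportionately because the max-loss switches which crop drives the
gradient. The signal-recovery check uses n ~ 2000 location-years. These
sizes are the package's own choices for its simulation studies; the
method itself has no dependence on them.

## Baselines

Single-crop baselines fit on the flattened histogram tensor (8,640
features at full scale, row-major in (time, bin, band) so band varies
fastest):

* **Ridge** — exact closed-form solution of
  \(\min \|y - Xb\|^2 + 0.05\|b\|^2\) via the dual n x n system
  (n << p makes this cheap and exact; generic solvers parameterize the
  penalty differently, which would silently change the stated 0.05).
* **Lasso** — coordinate descent (`glmnet`, `standardize = FALSE`) at
  penalty 0.05 under the `(1/2n)`RSS convention.
* **Random forest** — 150 trees, maximum depth 20 (`ranger`).
* **Regression tree** — maximum depth 12 (`rpart`, `cp = 0`,
  `minsplit = 2`).
* **DFNN** — nine hidden FC-50 layers, batch norm on hidden layers,
  ReLU, linear output; Adam on the Euclidean (mean-squared) loss.
* **3D-CNN** — 3x3x1 kernels over (time, bin, band) with one input
  channel, two max-pools (4x4x2, 2x2x1), FC-256, FC-128, linear output.
  Pooling strides default to the pool size; both unstated in the source
  description and documented here.

## The synthetic generator

There is no public simulator for this problem; the generator is this
package's own, designed as the simplest structure that reproduces the two
qualitative phenomena the method is about:

1. **Transfer between crops.** A standard-normal latent `z` per
   location-year drives both yields:
   \(Y^c = \mu_c + \sigma_c(\rho z + \sqrt{1-\rho^2}\,u^c) + \varepsilon\),
   with `rho = 0.8` by default, so a representation learned for one crop
   is useful for the other.
2. **Harder early-season forecasts.** Pixels of band `j` at composite `t`
   are drawn around \(\mu_j + \alpha_j\, g(t)\, z\) with a nondecreasing
   ramp `g` (linear 0 to 1 by default): the latent becomes progressively
   more visible as the season advances, so July truncation genuinely
   removes information.

Yield moments default to the observed Corn Belt summary statistics (corn
146.68 ± 36.03, soybean 45.02 ± 10.08 bu/acre). Label coverage is
likewise calibrated to the observed record counts — 13,992 corn and
12,502 soybean records against 1132 × 15 and 1076 × 15 possible
location-years give default per-entry label probabilities of 0.824 and
0.774 (at least one label is always kept) — so, as in the real data, not
every location-year carries both yields. Irreducible yield noise
defaults to 8 (corn) and 2.5 (soy) bu/acre — roughly 5% of the mean,
a plausible county-measurement error scale — and is the error floor no
predictor can beat. Band baselines are plausible crop-canopy reflectances
(dark red/blue, bright near-infrared) and Kelvin temperatures; the latent
shifts them in the agronomically expected directions (healthier seasons:
brighter NIR, darker red and shortwave infrared, cooler canopy). Cropland
is a jittered contiguous ellipse covering roughly half the grid; the
default grid is 64 x 64 (histogram outputs are size-independent, so the
grid only affects sampling noise per bin).

Every location-year draws from its own seeded substream in a fixed order
(latents, mask geometry, cropland pixels, then background pixels), so the
streaming histogram path and the full raster materialisation are
bit-identical where they overlap — the test suite exploits this as a
dual-route cross-check of the whole histogram pipeline.

A transparent linear reference (`oracle_predictor()`) regresses yields on
per-(time, band) histogram means. Under the generator's linear yield link
it recovers the signal up to irreducible noise, so its held-out RMSE is
the floor learned models are compared against.

**What the generator does not emulate:** spatial autocorrelation of
weather, crop rotation, realistic cloud contamination, label scarcity
patterns, and any nonlinearity in the yield link. Passing tests on this
generator therefore demonstrate that the pipeline, architecture, loss,
and training loop work as specified and can recover a known signal — not
that the method attains any particular accuracy on real MODIS/USDA data.

## Degenerate inputs and numerical edges

* A band that is constant across training frames widens its bin range by
  a relative 1e-6 so edges stay strictly increasing.
* Zero counted pixels for a (time, band) produce an all-zero histogram
  column with a warning, never an error, because downstream layers treat
  all-zero slices as "no data".
* The reference predictor falls back to a ridge-stabilized solve (jitter
  proportional to the Gram diagonal) when its design matrix is singular.
* `rho = 1` with zero yield noise makes both yields exact affine
  functions of the latent — used as an exactness test.
* Max-pool padding uses `-Inf` so padded cells can never win the max;
  pooling windows are disjoint (stride = size), so the gradient scatter
  cannot collide.

## Known limitations

* The engine is CPU-only and tuned for the fixed architecture sizes; it
  is not a general deep-learning framework.
* Under the max-loss, each head receives only the iterations in which
  its crop's term attains the maximum — roughly half the update budget.
  At strongly shortened schedules this undertrains the dual model
  relative to single-head variants trained with the same iteration
  count, so the dual model's advantage (a property of training to
  convergence) can shrink, vanish, or reverse at reduced scale; the
  package's reduced-scale ablation results should be read with that in
  mind.
* Training at the full 4000-iteration recipe takes minutes per model on
  one CPU; the experiment protocols are therefore usually run at the
  reduced scale above.
* Real-data reproduction (MODIS, cropland layers, agency yield records)
  is out of scope: no downloader is included, and the published
  real-data error tables are not reproduced here.
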