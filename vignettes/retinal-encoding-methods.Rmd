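---
title: "Methods: convolutional and recurrent encoding models of retinal ganglion cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: convolutional and recurrent encoding models of retinal ganglion cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Retinal ganglion cells (RGCs) transform a movie falling on the retina into
firing rates. A long-standing system-identification question is whether a
trained encoding model not only *predicts* those rates but also *recovers
the circuit elements* — the bipolar-cell-like subunits, their spatial
receptive fields (RFs) and biphasic temporal filters — that generate them.
`retinacoder` implements this program end to end in R: a ground-truth
simulated retina, two trainable encoder families (a feedforward CNN and a
convolutional-recurrent CRNN), Poisson-likelihood training, and the
analysis toolbox that scores what the models learned (STA receptive
fields, SVD factorization, 2-D Gaussian fits, kernel importance indices,
pruning curves, and SSIM scene-complexity maps).

All numerical machinery — the convolutional forward pass, backpropagation
including backpropagation through time, and the Adam optimizer — is
implemented in base R matrix algebra. Gradients are exact and are verified
against central finite differences in the test suite.

## The encoder models

A stimulus window is the frame at the predicted time bin plus the 19
preceding frames (20 bins total; at 33 ms per bin this is about 660 ms of
history). Windows enter the first convolutional layer as a stack of 20
input channels, so each first-layer kernel is genuinely *spatiotemporal* —
this matters because the kernel-importance index below is computed from
the temporal factor of each first-layer kernel.

Each convolutional stage computes, with valid (unpadded) stride-1
cross-correlation,

    O_l = ReLU( batchnorm( W_l * O_{l-1} + b_l ) + noise ),

where the Gaussian noise (sd `noise_sigma`, default 0.1, train mode only)
acts as a regularizer. The order chosen is convolution, batch
normalization, noise, then ReLU. The second convolutional layer is spatial
over the first layer's feature maps. The readout is a dense layer through
a *parametric softplus*

    yhat = alpha * log(1 + exp(beta * x)),

with trainable scalars `alpha`, `beta` (initialized at 1, clamped at 1e-3
from below, overflow-safe with an exact linear asymptote), which
guarantees strictly positive predicted rates.

The CRNN inserts one recurrent layer between the second convolution and
the dense readout. Vanilla RNN, GRU and LSTM steps are implemented
(`rnn_step`, `gru_step`, `lstm_step`); LSTM is the default unit, with 32
hidden units and training sequences of 64 consecutive bins. Two readout
conventions exist because flattening a whole hidden-state sequence into a
single readout and reading each bin's hidden state separately are both
defensible; the package defaults to the **per-bin readout** (`readout =
"per_bin"`), since the model must emit one rate per time bin, and offers
`readout = "flat"` behind the same flag.

With the recurrent layer removed the CRNN forward pass is architecturally
identical to the CNN — one code path implements both.

## Training objective

Training minimizes the Poisson negative log-likelihood surrogate plus
three penalties:

    L = mean( yhat - y * log(yhat) )
        + l2 * sum over weight matrices ||W||^2
        + l1_conv1 * ||W_1||_1
        + l1_activity * mean(yhat)

Defaults: `l2 = 1e-3`, `l1_conv1 = 5e-4`, `l1_activity = 1e-3`. The
squared L2 norm (conventional weight decay) was chosen where the norm
order is ambiguous; the first-layer L1 penalty pushes kernels toward
compact RF-like shapes. The data term is averaged over all entries
(bins x cells) so the penalty balance does not depend on population size.

Optimization is minibatch Adam (default batch 1024--8192 windows,
learning rate 2e-3, optional cosine decay). The epoch cap is 1000 with
early stopping once the best epoch loss has not improved by a relative
1e-5 for 20 consecutive epochs; the best-loss weights are restored. After
training, batch-normalization statistics are frozen to the exact
statistics of the full training set, which makes evaluation mode fully
deterministic. Train/validation splitting for movie-style data should cut
time contiguously (first 80% / last 20%), never shuffle across time.

## The simulated retina

The canonical fixture (`build_demo_retina()`) is a two-RGC circuit built
from eight handcrafted subunits on an 8x8 pixel grid: four square blocks,
two Gaussian blobs and two oriented bars, mixing ON and OFF polarities.
Temporal kernels are biphasic differences of exponentials with peak
latencies of 3--5 bins; the rebound lobe scales with the peak latency so
every kernel changes sign within the 20-bin depth. Each RGC pools four
subunits (one subunit shared, so the two RFs overlap) through the cascade

    subunit filter -> half-wave rectification -> nonnegative pooling
    -> softplus(gain * drive + baseline)

with gain 2.5 and baseline 0.2, yielding a mean rate of roughly 3.5
spikes/bin with binary noise — a realistic dynamic range that keeps both
the rectifier and the softplus in their informative regimes. The cascade
mirrors the encoder family (ReLU hidden units, softplus output), so the
encoders can represent the simulator exactly; recovery failures are
therefore attributable to training, not to model mismatch. A `"modelII"`
catalogue preset swaps the first subunit for an oriented alternative, for
robustness experiments.

Poisson spike trains are sampled per trial and bin
(`sample_poisson_spikes`); trial averages converge to the rates as
1/sqrt(trials). Models are trained on the noise-free rates by default —
the question the fixture answers is representational, not statistical —
and spike-train targets are available as a mode.

What the simulator deliberately does *not* emulate: photoreceptor and
bipolar dynamics, adaptation, spatially correlated noise, eye movements,
and recorded-data nonstationarities. Passing the benchmark shows the
pipeline recovers a known circuit from clean LN-pooling data; it does not
by itself certify performance on biological recordings.

## Receptive-field analysis

- **STA** (`compute_sta`): response-weighted average of mean-subtracted
  stimulus windows; rate weighting covers spike counts and continuous
  rates in one definition, and mean subtraction makes the
  response-independent case exactly null.
- **Factorization** (`factorize_rf`): the 3-D filter is reshaped to depth
  x pixels and the leading SVD triplet taken. Raw SVD signs are
  arbitrary, so the spatial factor is normalized to a positive dominant
  lobe; the cell's ON/OFF polarity then appears as the sign of the
  temporal factor's largest lobe.
- **Gaussian RF fit** (`fit_gaussian_rf`): Levenberg--Marquardt least
  squares of an elliptical Gaussian, initialized at the absolute-peak
  pixel with moment-based widths, after flipping polarity so the peak is
  positive. A fit is flagged "no effective RF" when the map lacks a
  dominant peak (peak below 3x the median absolute value), the optimizer
  fails, or the fitted Gaussian explains less than 20% of the map
  variance — the last criterion is what actually rejects pure-noise maps.
  Flagged cells are excluded from RF-distance statistics. Ellipses are
  drawn at the 1-sigma contour.
- **RF distance** (`rf_cosine_distance`): both fitted densities are
  evaluated on the pixel grid and compared by 1 minus cosine similarity.
- **Spatial autocorrelation** (`spatial_autocorrelation`): Moran's I with
  binary rook (4-neighbour) weights, the common default on pixel
  lattices; constant maps return 0 with a warning.
- **Temporal regularity** (`temporal_regularity`): the index
  `mean( (||w_i| - max|w|| - eps) / (||w - mean(w)||_2 + eps) )` with
  `eps = 5e-4`. The typeset form of the numerator admits two parses; the
  absolute-deviation parse is the default (consistent with computing the
  index from kernel magnitudes so ON and OFF kernels score alike) and the
  signed parse is available via `parse = "signed_dev"`. A constant kernel
  scores exactly -1; a two-point kernel [0, M] approaches sqrt(2)/2.
- **Kernel-subunit matching** (`match_kernels_to_subunits`): sign-agnostic
  absolute-cosine scores with an exact optimal one-to-one assignment
  (bitmask dynamic program, not greedy), since ON/OFF polarity may be
  absorbed into downstream weights.

## Pruning

Reduced models are built by *masking*: a non-kept first-layer kernel's
post-normalization output is forced to exact zero (so no batchnorm shift
leaks through), and nothing is retrained — this keeps the experiment
deterministic and attributes any performance change purely to the removed
kernels. Kernels are ranked by `tCorr` (temporal regularity) or `spaCorr`
(Moran's I), descending, ties broken by kernel id. `pruning_curve`
evaluates mean per-cell CC and population CC at each kernel count.
Re-training after masking is a deliberate non-default; the training-free
variant is the documented behaviour.

## Scene complexity

Frames are sliced into square patches (default 18 px). SSIM between two
patches is computed as a *single global statistic* per pair (means,
unbiased variances and covariance plugged into the standard SSIM form
with C1 = (0.01 L)^2, C2 = (0.03 L)^2, L = 1 for [0,1] clips) — the patch
is already the locality unit, so no sliding window is used inside it.
Spatial complexity of a patch is 1 minus its mean same-frame SSIM to its
existing neighbours (up to 8; border patches use their actual count),
averaged over frames. Temporal complexity compares each patch at time t
with its neighbours *and itself* at t+1, dividing by n+1. Constant movies
score exactly 0; i.i.d. noise scores near 1. Cells are related to patches
by overlapping their 1-sigma RF ellipse with the patch rectangle (an
exact convex minimization, tested against a rasterization oracle).

## Problem sizes and numerical choices

The package's standard benchmark trains both encoders on 49,984 windows
of 8x8 binary noise (a multiple of the 64-bin training sequence) and
evaluates on 2,560 held-out windows; the CNN runs up to 500 epochs and
the CRNN up to 350, with minibatches of 4,096 windows under a cosine
learning-rate schedule from 1e-2 down to 1e-4 with a 40-epoch linear
warmup; under a decaying schedule the benchmark lets the schedule run to
completion (patience set to the epoch cap) because the loss can plateau
during the high-learning-rate phase and a premature stop would forfeit
the low-rate refinement that delivers the last percent of correlation. Two optimization details matter beyond speed, because with only
eight first-layer kernels a single dead unit is fatal to subunit
recovery: small noisy batches (or a full-rate start) occasionally kill a
kernel in the first epochs — its ReLU output and downstream weights
collapse together under the first-layer L1 penalty — which caps the
attainable CC near 0.98 and leaves a subunit uncovered. Three measures
make the death-free trajectory reliable across seeds: large (4,096)
batches, the warmup ramp, and explicit dead-kernel revival
(`revive_dead = TRUE`): at each epoch end during the first 60% of
training, any first-layer kernel whose mean activation has collapsed to
below 2% of the median is re-initialized together with its
batch-normalization slot, its downstream second-layer weights and its
optimizer moments. Since a dead kernel contributes exactly nothing, the
re-initialization never loses learned structure — it only restores the
kernel's chance to capture the still-unexplained subunit. These settings
give per-cell held-out correlations above 0.99 for both architectures on
a single CPU core.

Other numerical choices: batchnorm epsilon 1e-5; softplus computed in its
linear asymptote beyond beta*x = 30; predicted rates floored at 1e-300
inside the log only; ReLU subgradient 0 at the kink; Adam moments (0.9,
0.999, eps 1e-8); all containers are plain-text (JSON arrays at 17
significant digits, which round-trips doubles exactly — checkpoints
restore bit-identical predictions).

## Known limitations

- Training speed is BLAS-bound; the package is desk-scale by design and
  does not target GPU-scale movie datasets (the 90x90, 128-kernel
  configuration is expressible but slow to train in R).
- The Gaussian RF fit assumes a single dominant blob; center-surround
  structure is captured only through the fitted center lobe.
- `preprocess_movie` offers min-max normalization only; whether recorded
  movies should instead be z-scored is left to the caller (the choice is
  configurable at the call site).
- The recurrent state is reset at sequence boundaries; very slow neural
  dynamics spanning sequences are out of scope.
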