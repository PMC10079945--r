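---
title: "From 1D biosignal windows to binary images: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From 1D biosignal windows to binary images: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rasterspike)
```

## The problem

Spike sorting and EEG event detection both reduce to classifying short,
non-stationary 1D waveforms by *shape*. Most image-based approaches encode
the signal spectrally (STFT, wavelets), which costs O(N log N) or worse and
entangles shape with the analysis parameters. This package takes the
geometric route: draw the window. Each sample amplitude becomes a pixel
row, consecutive samples are joined by straight line segments rasterized
with Bresenham's integer algorithm, and the resulting bilevel image is a
faithful, parameter-light picture of the waveform that a 2D CNN can
classify. Rasterizing an n-sample window costs O(n) integer additions.

## The simulated spike data

Recordings are built from a cosine-times-Gaussian action-potential model

$$V(t) = A \cos\!\left(\frac{2\pi\,(t-\tau_{ph})}{\tau_1}\right)
\exp\!\left(-\left(\frac{2.3548\,t}{\tau_2}\right)^{2}\right)$$

where $\tau_1$ (s) is the oscillation period, $\tau_2$ (s) the envelope
width — 2.3548 = $2\sqrt{2\ln 2}$ ties $\tau_2$ to the envelope's full
width at half maximum and is fixed, not a parameter — and $\tau_{ph}$ a
phase offset. Three spike classes fire as independent homogeneous Poisson
processes (default 3.3 Hz each) over a 200-s recording sampled at 20 kHz;
placements whose 56-sample supports would overlap an existing spike are
rejected and redrawn, so every labeled window contains exactly one shape.
Gaussian white noise is added with

$$\sigma = \frac{\overline{\max_t |V|}}{\mathrm{snr}}$$

the mean peak template amplitude divided by the configured SNR. Tests
verify the empirical noise sd of spike-free stretches against this
definition to within 5%.

**Template parameters.** The three shipped parameter sets
(`default_spike_params()`) are (A, τ1, τ2, τph) =
(1.0, 1.2 ms, 0.9 ms, 0), (1.0, 0.45 ms, 0.9 ms, 0.2 ms) and
(1.0, 0.65 ms, 1.3 ms, 0): a slow biphasic wave, a fast offset triphasic
wave, and a longer multi-lobed oscillation, 0.7–1.8 ms long. They were
chosen once so that every pair has normalized cross-correlation below 0.9
(measured 0.23/0.56/0.60) — separable by shape, but not trivially.

**SNR convention.** The conventional signal-to-noise direction
(higher snr = cleaner signal) is used. Published per-SNR accuracy tables
for this kind of task sometimes *improve* toward the low end of the 0.5–2.0
sweep, which suggests a noise-to-signal reading in some sources; the
convention here is explicit and configurable, and the seven sweep levels
{0.5, 0.75, …, 2.0} are interpreted under it. Under this convention 2.0 is
the cleanest level of the sweep.

**What the generator does not emulate:** electrode drift, bursting and
refractory structure, correlated (1/f) background, waveform variability
within a class, and overlapping spikes (rejected by construction). Passing
tests therefore demonstrate that the encoding and classifier recover
shape under stationary Gaussian noise — not performance on real tetrode
data. The EEG-like generator (`simulate_binary_epochs()`) is likewise a
synthetic stand-in: AR(1) background vs. high-amplitude 3–8 Hz bursts;
real seizure dynamics are far richer.

## Preprocessing

The order is fixed: unit-L2 normalization of the whole recording, then a
whole-recording min–max rescale to [0, 1], then windowing. L2 scaling alone
cannot place a signed signal in [0, 1], so the affine rescale is required
before rasterization; it is applied per *recording* (not per window) so
relative amplitudes across windows survive. Epoch tables (EEG) arrive
already windowed from heterogeneous subjects, so there the rescale is per
row and segmentation is skipped.

Spike windows are centered on the annotated waveform peak; windows touched
by a second annotation of a *different* class are discarded (one shape per
image), and annotation-free tiles become the noise class. Because a
200-s recording is mostly noise, the noise class is randomly capped at 1.2×
the mean spike-class count to keep training unbiased. The split is a seeded
shuffle with `floor(0.30 × total)` training windows — floor, because
27,371 windows must yield exactly 8,211/19,160.

## Rasterization

With resolution $r$ (amplitude units per pixel row, default 0.0005) and $d$
dummy columns between consecutive samples (default 20), sample $i$ of an
$n$-sample window maps to pixel column $i(d+1)$ and row
$\mathrm{round}((1-v_i)/r)$ (row 0 = top = amplitude 1). The grid has
$1/r + 1$ rows and $(n-1)(d+1)+1$ columns — 2,001 × 1,156 for the default
56-sample window. Quantization rounds half *up* (deterministically), a
choice the underlying convention leaves open.

Consecutive sample pixels are joined with Bresenham's algorithm: decision
variable $\nabla_i = 2\Delta b - \Delta a$, updated by
$+2\Delta b - 2\Delta a$ after a diagonal step (taken when
$\nabla \ge 0$ — ties resolve toward the diagonal) and $+2\Delta b$ after
an axis step. The first-octant rule generalizes to all octants by swapping
axes when $|\Delta b| > |\Delta a|$ and stepping with the sign of each
span; arithmetic stays integer-only. Tests verify exhaustively (all offsets
$|\Delta| \le 50$, every octant) that the pixel sequence stays within half
a pixel of the ideal line, uses exactly $\max(|\Delta a|,|\Delta b|)+1$
pixels, and hits both endpoints.

Down-scaling for the network uses block max-pooling — an output pixel is
lit if any covered input pixel is — because interpolation would average a
1-pixel-wide trace into near-background values.

## The network

The classifier is a modified LeNet-5-style CNN: five same-padded 3×3
convolutions with ReLU, feature maps 128-64-32-32-16, each followed by 2×2
stride-2 max pooling; batch normalization sits between conv-4 and pool-4;
then flatten, a 512-unit fully connected ReLU layer, dropout 0.5 and a
softmax output (4 classes for spikes, 2 for EEG). Layer sizes follow

$$N_{out}^{conv} = \left\lfloor \frac{N + 2P - K}{S} \right\rfloor + 1
\qquad
N_{out}^{pool} = \left\lfloor \frac{N - K}{S} \right\rfloor + 1$$

(the standard convolution sign: with the kernel term *added* instead of
subtracted no published layer size is reproducible, so the subtractive
form is implemented). A 320×320 input is the unique simple geometry that
makes the flatten exactly 1,600 = 16 × 10 × 10 after five halvings, so
320×320 is the default input and `resize_for_model()` brings the
full-resolution images to it. Only the first and last feature-map counts
(128, 16) are canonical; the intermediate 64-32-32 default is a monotone
interpolation and fully configurable, as are the unstated dropout rate
(0.5), batch size (32) and loss (categorical cross-entropy, the standard
softmax pairing). Training uses RMSprop (squared-gradient decay 0.9,
learning rate 0.001, 20 epochs at full scale).

The implementation is native: channels-first `(C, H, W, B)` arrays, im2col
patch extraction and its col2im adjoint plus max pooling as compiled
kernels, convolutions as BLAS matrix products, and hand-derived backward
passes for every layer (verified against central finite differences to
~1e-9 relative error). He initialization, seeded; dropout and shuffling
draw from the training seed, and prediction is deterministic (dropout off,
batch-norm running statistics).

## Numerical and degenerate-input choices

- Half-up rounding everywhere a half-integer can occur (row quantization,
  percentage formatting): deterministic and platform-independent, unlike
  round-half-to-even on formatted output.
- Bresenham ties ($\nabla = 0$) step diagonally; the reversed line may
  therefore differ from the forward line exactly at tie pixels, which the
  property tests single out.
- Constant windows rasterize to a straight row; constant *recordings*
  cannot be rescaled (error). All-zero vectors cannot be L2-normalized
  (error). Metrics with empty denominators return `NaN` with a warning
  rather than a silent 0 or 100.
- Poisson placement rejects overlaps; at the default rates <1% of draws
  collide, and a bounded retry count turns pathological configurations
  (firing rate × support approaching 1) into a clean error.
- Batch-norm variance uses the biased (1/N) estimator with ε = 1e-5, and
  running statistics with momentum 0.9; a max-pool over equal values keeps
  the first (smallest-offset) pixel, making ties deterministic.

## Problem sizes used in tests and the acceptance run

The shipped end-to-end configuration (`desk_scale_config()`) is a reduced
instance chosen as this package's standard evaluation size: two 200-s
recordings at one SNR level (≈1,300 windows per spike class after the
noise cap, ≈5,500 windows total), raster resolution 0.005 with 4 dummy
columns (201×276 images), 64×64 network input with 16 feature maps per
stage, 10 epochs, 30/70 split. At seed 1 and SNR 2.0 this reaches 92.6%
four-class test accuracy in a few minutes on one CPU — consistent with the
above-90% regime reported for this family of encodings — while the
full-scale defaults remain available through `pipeline_config()`. Unit
tests use still smaller instances (tens of windows, 32×32 inputs) chosen
to exercise every code path rather than to measure performance.

## Known limitations

- The native network targets desk-scale studies; a GPU framework would be
  needed for the full 320×320/128-map configuration at realistic dataset
  sizes.
- Ground-truth annotations are assumed; there is no spike *detection*
  stage, no filtering, and no artifact rejection.
- The rasterized image width is $(n-1)(d+1)+1$ (1,156 for n = 56, d = 20).
  Some published figures quote 1,155 for this geometry — counting the last
  column index rather than the column count; the off-by-one is documented
  rather than chased.
- Accuracy at a given SNR depends on the template parameter sets, which
  are package defaults rather than canonical values; per-SNR accuracy
  tables are therefore reproducible in trend, not cell by cell.
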