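---
title: "Nucleus detection by proximity-map regression: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nucleus detection by proximity-map regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proxidet)
```

## The problem and the model

Counting and locating cell nuclei in stained tissue images is a
prerequisite for most quantitative histology. `proxidet` treats nucleus
detection as dense regression: every annotated center is expanded into a
small *proximity map*, a fully convolutional network learns to predict
that map pixel-to-pixel from the RGB image, and centers are read off the
predicted map as local maxima.

### Proximity encoding

For a pixel at Euclidean distance $D$ from its nearest annotated center,
the regression target is

$$y(D) \;=\; s\,\frac{e^{\alpha\,(1 - D/d)} - 1}{e^{\alpha} - 1}
\quad\text{if } D \le d, \qquad y(D) = 0 \text{ otherwise,}$$

with decay control $\alpha = 3$, distance threshold $d = 15$ px, and a
training-time value scale $s = 5$. The encoding equals $s$ exactly on a
center, decays continuously to zero at distance $d$, and is identically
zero farther away, so only small disks around nuclei carry positive
values. Distances are computed exactly from integer pixel centers to
real-valued annotation points; the package rejects approximate distance
transforms for this purpose because the encoding is the method's core
contract.

### Weighted mean squared error

Because most of a proximity map can be zero, a plain MSE admits a trivial
all-zero solution. The training loss for one image weights each pixel's
squared residual by $y_{uv} + \lambda\,\bar y$:

$$\mathcal L(\mathbf o, \mathbf y) = \frac{1}{2}
\sum_{u,v} \left(y_{uv} + \lambda\,\bar y\right)
\left(o_{uv} - y_{uv}\right)^2,$$

normalized by the pixel count, with $\lambda = 5$ by default and
$\bar y$ the mean of the image's gold map. Two consequences matter:

* With $\lambda = 0$ the background (where $y = 0$) carries no weight at
  all — predictions there are unconstrained.
* $\bar y$ is a per-image quantity. The package computes it on the *full
  source image's* map and carries it alongside cropped training patches.
  An all-background crop of an annotated image therefore still carries
  the uniform weight $\lambda\bar y > 0$. If $\bar y$ were recomputed on
  the crop itself it would vanish there and the background penalty would
  silently disappear for exactly the patches that need it.

For the configuration whose last layer is a sigmoid, the derivative of
the loss with respect to the last-layer pre-activation has the closed
form $(y_{uv} + \lambda\bar y)(o_{uv} - y_{uv})\,a_{uv}(1 - a_{uv})$;
the package keeps a sigmoid head (`network_spec(sigmoid_head = TRUE)`)
purely as the configuration in which this closed form can be tested
against backpropagation and finite differences. The production head is
linear: a sigmoid bounded by 1 cannot reach scaled targets of 5, so the
network regresses the scaled values directly.

### Architecture

`build_network()` constructs the residual encoder–decoder:

* an input transition (one 3×3 convolution), then `depth` (default 4)
  downsampling residual blocks. The first convolution of each block has
  stride 2; channel counts double at each downsampling except the last.
  Each residual block is two 3×3 convolutions with batch normalization,
  ELU after the first convolution and after the shortcut addition, and a
  projection shortcut where shapes change.
* `depth` upsampling residual blocks, each beginning with a kernel-2 /
  stride-2 transposed convolution and concatenating the mirrored
  downsampling block's output. With odd sizes the downsampling floor
  makes paths asymmetric (75 → 37 → 74); upsampled maps are zero-padded
  on the bottom/right to match before concatenation.
* a multi-context aggregation path: each downsampled output is carried to
  full resolution by a single transposed convolution (kernel = stride =
  its downsampling factor), projected to the base width, and summed with
  a projection of the decoder output. Summation (rather than
  concatenation) keeps the output transition's input width fixed; which
  combiner the original design used is not determinable, so this is a
  package design choice.
* an output transition of two 3×3 convolutions producing the
  single-channel map.

Stride-2 convolutions pad one pixel on the top/left only, which makes
the output size exactly `floor(H/2)` for both parities; the shortcut
projection samples from offset 1 with a 1×1 stride-2 convolution for the
same size rule. Dropout (rate 0.5) acts after the convolutions of the
last two downsampling blocks, during training only.

Blocks are indexed 1..(2·depth+2) from input to output; with the default
depth there are 10. `freeze_blocks(net, k)` excludes blocks 1..k from
updates and pins their batch-norm statistics, which supports the
transfer-learning experiments (fine-tune everything, or only the last
few blocks). The multi-context projections are grouped with the output
transition for freezing purposes, since they feed it directly.

There is no deep-learning framework dependency: convolutions and
transposed convolutions are im2col/GEMM kernels in compiled code, and
the backward pass is hand-written and verified against central finite
differences through the whole network in the test suite.

### Training

SGD with Nesterov momentum 0.9, learning rate 0.01, weight decay 1e-6,
batch size 4, with per-iteration dynamic cropping of patches, joint
dihedral (right-angle rotation + mirror) augmentation, optional shifts
with reflect padding and optional smooth elastic distortion, and
per-patch per-channel standardization. Validation F1 (at the best
threshold on a grid) is evaluated periodically; when it fails to improve
for the patience window the learning rate is divided by 10, never below
1e-4. Right-angle rotations are preferred to arbitrary angles because
interpolation smears the sparse label maps; arbitrary-angle rotation is
deliberately not offered.

Mixed-source training follows $\gamma \mathcal L_T + \mathcal L_A$. In
the batch implementation both partial losses are normalized by the
*total* batch size, so $\gamma = 1$ reproduces naive pooling of the two
sources exactly (gradient-identical on the same batch), and as
$\gamma \to \infty$ the normalized gradient direction converges to the
target-only direction. Auxiliary subsampling fractions select
`round(f * N)` images deterministically under the training seed.

### Detection and evaluation

At test time the full image is standardized and passed through the
network once. Values below $\xi \cdot \max(\mathbf p)$ are suppressed
and local maxima are extracted: a detection is a pixel not smaller than
any neighbor within `min_distance` (default 6 px, about the smallest
plausible nucleus radius under the $d = 15$ encoding; the neighborhood
definition is a package choice since none is prescribed). Connected
equal-valued plateaus collapse to their centroid, border pixels are
eligible, and the relative threshold makes detection invariant to
positive rescaling of the map. Predicted maps are not clipped to
$[0, s]$ first — thresholding relative to the map's own maximum makes
clipping unnecessary.

Detections are matched to annotations one-to-one by minimum total
Euclidean distance (a Jonker–Volgenant shortest-augmenting-path solver
written for this package, since no linear-assignment solver is available
in the dependency set; it is tested against exhaustive enumeration).
Pairs farther apart than the 16-px gold-region radius receive a sentinel
cost larger than any achievable total and are dissolved into FP + FN
afterwards. Precision, recall, F1 and the mean Euclidean distance over
true positives follow; PR curves pool TP/FP/FN counts over images
(micro-averaging), and $\xi$ is selected as the grid value with the best
pooled validation F1, ties broken toward the larger (more conservative)
threshold. Degenerate conventions: with neither detections nor
annotations all metrics are 1; otherwise an empty denominator yields 0.

## The synthetic study conditions

Real H&E crops of the kind the method targets are not redistributable,
so the package ships a seeded generator of H&E-like tiles
(`synth_style()`, `generate_image()`): eosin-pink background with
low-frequency texture, unannotated hue-shifted clutter smudges (soft
ellipses between stroma and nucleus color — stand-ins for stromal
debris and dense-chromatin lookalikes), and hematoxylin-dark
anti-aliased elliptical nuclei with radial intensity falloff, per-nucleus
color jitter, controlled size/eccentricity ranges and a configurable
fraction of touching nuclei (placed by perturbing existing centers —
controllable overlap without physics simulation). Centers are
real-valued (row, col), 0-based, pixel centers at integers; this single
convention rules the whole package including CSV I/O (`x` = column,
`y` = row).

The desk-scale study conditions used by the tests and the acceptance
script are: 64×64 tiles, 4–9 nuclei with semi-major axes 3–6 px,
eccentricity up to 0.6, 20 % touching nuclei, 3–8 clutter smudges,
noise sd 4 — a density and contrast a practitioner would call a
moderately busy, clearly stained tissue patch at this tile size. The
corpus is 210 images split 150 train / 30 val / 30 test; the network is
the `base_width = 8` variant of the architecture (the doubling rule and
block structure are unchanged); training runs a few hundred iterations
of the standard recipe. These sizes are the package's CPU-scale defaults
and are stated here so results are interpretable.

What passing at desk scale shows — and what it does not: the synthetic
tiles exercise touching objects, scale variation, stain-like color
statistics and cluttered backgrounds, so they validate the machinery
(encoding, loss, optimization, detection, matching) end to end. They do
not reproduce real tissue's nuclear texture, focus variation, staining
artifacts or organ-level diversity, so absolute metric values on
synthetic data say nothing quantitative about any real dataset.

### A note on the λ ablation at desk scale

On 64×64 tiles with $d = 15$, a handful of nuclei already makes most of
the map nonzero, and on clutter-free synthetic backgrounds a smooth
convolutional network keeps background predictions low even when
$\lambda = 0$ leaves them completely unsupervised — in probe runs the
$\lambda = 0$ model detected as well as the $\lambda = 5$ one. The
mechanism that makes small $\lambda$ fail in practice is background
structure that *resembles* nuclei: without background weight the network
is free to score clutter highly, producing false positives. That is why
the generator's clutter component matters for this experiment, and why
the λ-ablation check should be read as a direction-of-effect test under
cluttered conditions, not as a reproduction of any particular margin.

## Numerical choices

* Batch-norm: biased variance, epsilon 1e-5, running-moment momentum
  0.1; frozen blocks normalize with (and stop updating) running moments.
* Weight init: He-normal for convolutions, zeros for biases, unit gain
  for normalization — drawn from R's RNG so `set.seed()` reproduces a
  network bit-for-bit; all randomness (corpus, init, cropping,
  augmentation, dropout) flows from explicit seeds and runs are
  reproducible bit-for-bit on a fixed BLAS.
* Conv biases are retained even though a following batch norm cancels
  them exactly (their gradient is provably zero); they matter only in
  the unnormalized output convolution.
* Divergence guard: a non-finite loss aborts training and restores the
  last snapshot (taken every `snapshot_every` iterations).
* Standardization guards constant channels with an epsilon, mapping them
  to zero.
* Proximity maps serialize as 32-bit float TIFF in units of the encoding
  scale; gold maps round-trip exactly, and out-of-range values are
  clipped with a warning (the TIFF writer available defines storage only
  on [0, 1]).

## Known limitations

* Single-CPU double-precision training: desk-scale problems train in
  minutes, but the full-scale recipe (200×200 patches, 1e5 iterations)
  is out of reach of this implementation and is retained as
  configuration only.
* The local-maxima neighborhood and the plateau rule are deterministic
  package conventions; other reasonable choices (e.g. 8-connected
  maxima without a distance constraint) change detection counts on
  plateau-heavy maps.
* The elastic-distortion field uses bilinear control-grid upsampling
  (spacing 32 px, magnitude in pixels); it is mild by default and off in
  the desk profile to keep sparse labels intact.
* Whole-slide inputs, stain normalization and segmentation masks are out
  of scope.
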