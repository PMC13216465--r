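---
title: "Annotation-free polyp segmentation: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotation-free polyp segmentation: models, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polypseg)
```

## The problem

Supervised polyp segmentation needs pixel-accurate expert masks, which are
expensive and never cover rare phenotypes. `polypseg` implements the
opposite regime: one-class, annotation-free training. Only polyp-free
("normal") colonoscopy frames are used; supervision comes entirely from a
procedural simulator that paints plausible lesions into normal frames, and
the network learns to segment *deviations from stored prototypes of normal
mucosa*. At inference, real lesions are segmented by the same mechanism,
without a single annotated training image.

## The lesion simulator

### Contour model

A lesion footprint is a perturbed circle in polar coordinates,

$$ r(\theta) = 1 + \sum_{i=1}^{n} \xi_i\, \omega_i \sin(i\theta + \phi_i),
\qquad \omega_i = 1/i^2,\; \phi_i \sim U(0, 2\pi),\; \xi_i \sim U(0,1), $$

with $n = 1000$ harmonics. The quadratic amplitude decay (a Brownian-noise
spectrum) suppresses high frequencies, giving smooth organic outlines; the
perturbation is bounded by $\sum_i \xi_i \omega_i < \pi^2/6$. The contour
is discretized at 50 equally spaced angles, densified by a factor of 10
with closed periodic cubic splines on the Cartesian boundary (periodicity
avoids a seam at $\theta = 0$), rescaled so the larger bounding-box side
spans 90% of a 512 px grid (centred; the margin protects later
transforms), and filled by even-odd scanline rasterization. A template set
of 1000 such masks is pre-generated; `buildTemplateSet()` reproduces it
from a seed.

One written ambiguity had to be resolved: the contour formula subscripts
the scale $\xi$ per harmonic, while it can also be read as a single shared
scale. We follow the formula (independent $\xi_i$ per harmonic) and
expose `sharedXi = TRUE` for the other reading.

### Mask transformation and placement

A sampled template is downscaled to 60% of its extent, randomly rotated,
randomly translated (conservative bounding-box bookkeeping keeps the
lesion inside the frame), elastically deformed, scaled globally by
$s \sim U(0.2, 0.9)$, and resampled onto the image grid. All steps are one
inverse-mapped bilinear warp, so forcing identity parameters reproduces
the template exactly — which is how the tests pin the geometry down. The
elastic field is an $8\times 8$ control grid of uniform displacements,
bilinearly upscaled, Gaussian-smoothed and capped at 5% of the image size
(no parameters for it are published; these are package choices).

Placement is restricted to the anatomically valid region: the Otsu
threshold of the image luma, clamped into a [20, 50] guard band (a hard
floor removes black borders and overlays, the cap prevents splitting
uniformly bright mucosa), followed by a $3\times3$ opening. The final mask
is the element-wise product of the valid region and the transformed
template; if the intersection is empty or loses more than half of the
lesion, placement is re-drawn (at most 10 times, then the image is
reported unusable).

### Content synthesis

Three strategies fill the mask, drawn with probabilities 0.4 / 0.4 / 0.2,
each mimicking a clinical phenotype class of the NICE taxonomy:

* **patch**: the image itself, passed through a transform table
  (flips, rotation, anisotropic x-scaling; intensity multiply 1.5–2.0,
  gamma 0.5–1.5, Gaussian blur $\sigma = 5$, hue/saturation shift
  $\pm 10$), each row firing independently with its probability —
  homogeneous lesions slightly lighter than mucosa. The intensity range
  only brightens; it is applied as printed, with a config override.
* **texture**: an external texture, colour-matched to the image by
  iterative distribution transfer and structure restoration, then
  transformed — dark, heterogeneous lesions.
* **hybrid**: the convex combination $(1-\alpha) I' + \alpha T_c'$ with
  $\alpha \sim U(0.3, 0.7)$ — brownish intermediate lesions. At
  $\alpha \in \{0, 1\}$ it reduces bit-for-bit to the parent modes under
  shared seeds, which the tests assert.

Compositing darkens the base image by $1 - \lambda B$ where $B$ is the
peak-normalised Gaussian blur of the mask ($\sigma_s = 7$ px,
$\lambda = 0.3$; no published values, both exposed in the API), then
overlays content with $B$-weighted feathering. The blur kernel is
truncated at $3\sigma$, so pixels outside the shadow band are bit-identical
to the base image — the compositing-locality invariant the test suite
checks. The shadow is applied once, at compositing (whether the hybrid
branch re-applies it is unspecified in the source description).

### Colour transfer

The texture recolouring is the classic iterative 1D-projection scheme:
per iteration, both colour clouds are projected onto three orthonormal
axes, each 1D marginal is matched by monotone quantile mapping (linear
interpolation between order statistics, stable-sort ties), and the result
is rotated back. The first iteration uses the RGB identity basis, later
ones seeded random rotations; ten iterations are the default because the
marginal mismatch plateaus on fixture images well before that. A final
restoration step recombines the recoloured low-pass with the original
high-pass (Gaussian split, $\sigma = 2$ px), which satisfies the intended
contract — colour from the reference, structure from the texture — without
the heavier variational "regrain" refinement, which is out of scope.

## The segmentation network

A frozen ResNet18-style encoder (stem + stages 1–3) yields features at
64/128/256 channels and 1/4–1/16 resolution. A fixed **memory bank** stores
the feature pyramids of $N = 30$ randomly selected normal images, encoded
once and never updated. For an input, the candidate difference map against
prototype $i$ is the channel-preserving element-wise squared difference;
the selected map $D^*$ minimises the total sum over all elements
(channel-preserving because the attention below averages over channels;
squared rather than rooted keeps the map smooth at zero). Spatial
attention cascades coarse-to-fine: $M_3$ is the channel mean of the
coarsest $D^*$, and each finer map is its own channel mean times the
bilinear $\times 2$ upsampling of the coarser one.

The trainable head concatenates features with $D^*$ per scale, applies a
$3\times3$ convolution, instance norm and ReLU, a coordinate-attention
block, and cross-scale additive fusion (coarser scales upsampled and
convolved into finer ones, all at a common width so the addition is
element-wise). Fused features are modulated by the attention maps and
decoded by four $\times2$ progressive-upsampling stages with $1\times1$
skip connections from the finer modulated scales, ending in a sigmoid.

Three deliberate numerical choices:

* **Pretraining.** No pretrained weights ship with (or can be loaded by)
  this package; the frozen encoder is He-initialised from a fixed seed.
  Random multi-scale convolutional features are weaker than pretrained
  ones but preserve input differences, which is all the discrepancy
  mechanism needs on fixture data; the test suite's localisation
  invariants (attention higher inside a synthetic lesion than outside)
  hold with the random encoder. `calibrateEncoder()` additionally sets
  each encoder normalisation layer's running statistics from a sample of
  normal images (layer by layer in forward order) — the statistics that
  pretrained weights would otherwise carry — keeping activations
  well-scaled through the residual stages and measurably sharpening the
  discrepancy contrast.
* **Normalisation.** The head uses per-channel *instance* normalisation
  with affine parameters instead of batch statistics: batch items are
  processed independently in this implementation, instance norm behaves
  identically at train and eval time, and the parameter count (2 per
  channel) is the same. Additionally, the concatenated head inputs and
  the attention-modulated features pass through *parameter-free*
  per-image standardisation: raw discrepancy magnitudes vary by orders of
  magnitude from image to image, and without this conditioning the
  shared-weight gradients are dominated by whichever image in the batch
  happens to carry the largest scale.
* **Widths.** The exact fusion/decoder widths are not published. The
  reference configuration (`modelConfig()`: fusion width 512,
  coordinate-attention bottleneck 160, decoder entry 512, stages
  512/256/128/70) was chosen so the instantiated network reproduces the
  published parameter budget: 19.05M total, 16.27M trainable, with the
  frozen encoder share (2,782,784) matching a ResNet18 stem+stages-1..3
  exactly. `countParameters()` reports the exact integers.

Eq.-level selection is per scale: each scale independently picks its
closest prototype (the selection rule is written per scale; nothing ties
the three scales to one memory item).

## Training

Batches mix normal images (all-zero masks) and freshly simulated lesion
pairs 50/50 (the ratio is not published; balanced batches give both terms
of the one-class objective equal gradient weight). The loss is pixel-wise
focal loss, $-\alpha (1-p_t)^\gamma \log p_t$ with $\alpha = 1$,
$\gamma = 4$, reduced by mean over pixels then over the batch. The
optimiser is SGD (momentum 0.9, weight decay $3\times10^{-4}$), learning
rate $0.01$ with cosine annealing to zero over the epoch budget. Model
selection keeps the checkpoint maximising $(\mathrm{IoU}+\mathrm{Dice})/2$
on a held-out 20% validation split; validation ground truth is
synthetic — pairs generated from validation normals with fixed, held-out
seeds, so the selection metric is stable across epochs (how the original
protocol formed validation truth is unstated; synthetic validation is the
package's choice). Within the selection score, pure normal validation
images (empty ground truth) are scored by specificity — the fraction of
correctly background pixels — rather than by IoU/Dice, which are
degenerate there: a single false-positive pixel would score 0 while a
pristine empty prediction scores 1, making an untrained all-background
model unbeatable. The checkpoint's reported IoU/Dice remain the
synthetic-pair values. The untrained (epoch-0) score is logged first, so
any training run documents its own improvement. Divergence (non-finite loss)
aborts with a diagnostic rather than silently continuing.

### Problem sizes and the smoke scale

The reference protocol (256 px inputs, batch 8, 5000 epochs, $N = 30$) is
what `trainConfig()` and `modelConfig()` encode. The package's *smoke
scale* — `smokeTrainConfig()` + `smokeModelConfig(128)`: 64 px fixture
crops upscaled to 128 px, a narrow head (fusion width 32), $N = 30$
memory prototypes, 30 epochs of 8 batches on 200 fixture normals — is the
scale at which the test suite demonstrates end-to-end learning on a CPU
in a few minutes. Upscaling the crops (rather than training at the crop
resolution) halves the fraction of boundary pixels per lesion, which the
overlap metrics are sensitive to. Two further knobs exist specifically
for short-budget runs, both neutral at reference scale:

* `synPoolSize` bounds the set of simulator pairs a run draws from
  (default `NULL`: a fresh pair per batch slot, the reference behaviour).
  A short run must revisit each lesion several times to consolidate;
  with thousands of epochs the bound is unnecessary.
* `calibrationImages` sets the encoder normalisation statistics from
  that many training normals before the bank is built (see below).

What the smoke scale shows — and what it does not. Starting from a
random-feature encoder, the selection score (synthetic-pair overlap plus
specificity on normal validation images) improves over the run, the
training loss falls several-fold, and false-positive rates on normal
validation images drop to the low percent range. The
absolute held-out synthetic-pair Dice, however, plateaus low (of order
0.1–0.25 depending on how training pairs are drawn): with a random
frozen encoder, two different normal images differ in feature space
about as much as a lesion differs from its own background, so the
discrepancy signal that drives the architecture is noisy for every image
that is not itself a memory prototype. A pretrained encoder — which the
package deliberately does not bundle — is what makes normal mucosa map
to similar features and lesions stand out; this ceiling is a property of
the fully self-contained configuration, not of the architecture. The
untrained epoch-0 head is a degenerate baseline: it emits a near-uniform
probability slightly above threshold, predicting essentially the whole
frame and earning a deceptively high raw Dice from coverage alone, which
is why improvement is measured on the selection score.

## Inference and post-processing

Probability maps are computed at the model resolution and bilinearly
resized to the native image size; the decision threshold is 0.5 (no
published value; exposed as an argument). Refinement is morphological
closing with a $5\times5$ square element, hole filling by 4-connected
border flood fill (equivalent to per-component filling for masks whose
holes do not touch the border), and retention of the largest 8-connected
component, ties broken by raster scan order. The pipeline is idempotent
and never increases the component count.

## Evaluation harness

IoU and Dice are computed from exact pixel confusion counts; the empty
prediction against empty truth is defined as 1.0 (it cannot occur on
all-lesion test sets, but the harness is total). Dataset aggregation uses
the population standard deviation (denominator $n$); the paired t-test
uses the sample standard deviation, each the standard convention for its
context. The group-sampling protocol draws, per trial, five disjoint
groups of 100 images without replacement (whether the original groups may
overlap is unstated; disjoint sampling is the stricter reading), averages
the group means, and reports mean and standard deviation over 50 trials.
Degenerate paired differences (zero variance) are an error — no p-value is
fabricated. `addBiasPatch()` paints a 64 px black square in the lower-left
corner (no published size; 64 px covers the fixture thumbnail with
margin), neutralising the corner-thumbnail shortcut feature.

## What the fixtures do and do not show

The fixture generator emulates the statistics that matter to this
pipeline: a reddish-pink low-frequency mucosa palette (seeded multi-octave
value noise in HSV), vignetting, specular highlights, the corner-thumbnail
class bias, and noise-based texture patches with controllable palettes.
It does not emulate specular geometry, instrument occlusion, stool/debris,
motion blur or interlacing, nor real polyp morphology. Passing tests
therefore demonstrate that the simulator contracts hold, that the
memory/attention mechanism localises synthetic anomalies, and that the
training loop learns end-to-end at smoke scale — not that clinical-grade
accuracy transfers to real endoscopy, which requires the real corpora and
the full-scale protocol.

## Known limitations

* The encoder is architecture-faithful but not pretrained; real-data
  performance would require loading pretrained weights, which the package
  deliberately does not bundle.
* Single-lesion simulation only; multi-polyp frames are out of scope.
* Frame-level processing; no temporal consistency across video.
* CPU-oriented numerics (double precision, BLAS-backed); no GPU path.
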