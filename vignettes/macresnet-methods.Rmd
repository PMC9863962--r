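---
title: "Attention-crop residual networks and knowledge distillation for eyelid-tumor pathology: methods and design notes"
author: "macresnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{macresnet methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(macresnet)
```

## The problem

Digitized pathology slides of eyelid tumors are gigapixel rasters in which a
pathologist outlines lesion regions and assigns a slide-level diagnosis among
three malignant classes — basal cell carcinoma (BCC), meibomian gland
carcinoma (MGC) and cutaneous melanoma (CM) — against normal tissue. The
package implements a complete patch-based pipeline for this setting:
slides are tiled into overlapping patches, cleaned, classified by a
convolutional network, and lesions are localized by per-class segmentation
networks whose patch outputs are reassembled into a slide-level mask.

Everything runs on a compact CNN engine built into the package (im2col
convolutions with analytic backprop, batch normalization, max/pyramid
pooling, Adam), so the full method is testable on a single CPU at miniature
scale. The engine's gradients are verified against finite differences in the
test suite.

## Patch extraction

Windows of `patch_size` (default 512) are slid at `stride` (default 256,
i.e. 50% overlap) over the slide; half-open windows `[r, r+512) x [c, c+512)`
that do not fit entirely inside the image are dropped rather than padded —
the overlap already covers the interior, and padding would fabricate tissue.
A window is kept only when its lesion-mask coverage is **strictly** greater
than `coverage_threshold` (default 3/4): a window at exactly 0.75 is
discarded. The "more than 3/4" rule exists to keep patches that are
dominated by lesion, so the patch label can safely inherit the slide label.

Tiles containing only scattered tissue compress extremely well, so the
cleaning rule is an *encoded-size filter*: the tile is encoded (PNG) and
discarded when the byte length falls below `min_encoded_bytes`
(default 330 x 1024). Because the on-disk codec behind such a rule is
inherently format-dependent, the codec is configurable, the threshold scales
as `(patch_size/512)^2` when tiling at other sizes, and an alternative
tissue-fraction filter is available behind `filter_mode`.

Per-channel standardization statistics are fit on the **training patches
only** and reused for validation, test and inference data; `fit_normalization`
refuses zero-variance channels instead of silently dividing by zero.

Normal slides (label 0) carry an empty lesion mask by construction, so the
strict coverage rule would discard every window. The dataset builder
(`build_patch_dataset`) therefore harvests all windows of normal slides as
label-0 patches — the whole slide is normal tissue — while tumor slides
follow the coverage rule. `extract_patches` itself always applies the mask
contract.

## The classifier family

The backbone is a ResNet50-style bottleneck skeleton with four configurable
additions; every switch preserves the output interface, so all ablation
placements are constructible from configuration alone.

* **SampleInput stem.** The single 7x7 stride-2 stem convolution is replaced
  by three stacked 3x3 convolutions. Stacked 3x3 convolutions at stride 1
  grow the receptive field as 3 -> 5 -> 7, so the composite sees exactly the
  7x7 field of the layer it replaces while being deeper and cheaper. The
  stride-2 step is placed on the **third** convolution: putting it on the
  first convolution would dilate the later 3x3 fields to an 11x11 composite
  and break the same-perceptual-field property. The test suite audits the
  footprint by backpropagating a one-hot gradient through the stem
  (`stem_receptive_field`).
* **DARes stages.** A stage's bottleneck stack is wrapped in an *outer*
  residual: the projected stage input (shallow), the projected output of the
  middle block (middle) and the stage output (deep) are summed before the
  final activation. The middle tap is block `ceiling(k/2)` of a `k`-block
  stage, projected by 1x1 convolution + batch norm. This is the minimal
  wiring that is both "double-layer nested" and fuses shallow, middle and
  deep feature maps; the attention mechanism lives in the BACM head, not
  inside the block. Default placement is layer2 + layer4, the
  best-performing ablation position.
* **SPP head.** Spatial pyramid pooling averages the final feature map over
  1x1, 2x2 and 4x4 grids (configurable) and concatenates the results,
  producing a fixed-length descriptor — `channels * sum(levels^2)` — for any
  input size at least as large as the largest grid. This is what lets one
  parameter set serve multiple input resolutions.
* **Width multiplier and depth.** `width_multiplier` scales all channel
  counts and `blocks_per_stage` the depth, so desk-scale miniatures
  (`miniature_config()`: width 1/8 or 1/16, two blocks per stage, 64-px
  inputs) exercise identical wiring to the full-width model.

The plain **student** configuration (`student_config`) keeps class count,
width and depth but drops all three additions: single 7x7 stem, plain
stages, global average pooling.

## BACM: attention-guided crop training

Before the fully connected layer, a 1x1 convolution produces `X` attention
maps (default 32) from the final feature map. For each image one map is
selected uniformly at random (seeded), min-max normalized,

$$A^{*} = \frac{A - \min A}{\max A - \min A},$$

and binarized at threshold $\theta_c$ (default 0.5) with a **strict**
inequality. The binary mask is upsampled to image resolution (nearest
neighbor), its tight bounding box is cut from the *original* image, and the
crop is bilinearly resized to the network input size — the
"AttentionPicture". The batch loss is the mean of the original-pass and
crop-pass losses, each weighted 1/2.

Degenerate cases are handled so training can never halt: a constant
attention map cannot be rescaled and is flagged degenerate, its mask falls
back to all-ones, and the crop becomes a plain resize of the full image.
Raising $\theta_c$ can only shrink the mask (tested property). The crop
geometry is a single bounding box over all positive pixels rather than
per-component boxes — the simplest reading of cropping "according to the
generated mask" — and the crop pass goes through the same
normalization/augmentation contract as the originals.

## Losses

For imbalanced classes the hard-label loss is the focal loss
$\mathrm{FL}(p_t) = -\alpha_t (1-p_t)^{\gamma} \log p_t$ with defaults
$\alpha_t = 0.25$, $\gamma = 2$; $\gamma = 0$, $\alpha_t = 1$ recovers
cross-entropy. Label smoothing (factor 0.1) is provided as a comparison
option.

Knowledge distillation uses temperature softmax
$\mathrm{softmax}(z/T)$ and the loss

$$L_{KD} = (1-a)\,L_f(\mathrm{SHP}, y) + a\,T^2\,\mathrm{KL}(\mathrm{TSL}\,\|\,\mathrm{SSP}),$$

$$T_{loss} = \tfrac12 L_{KD} + \tfrac12 L_f(\text{attention pass}, y),$$

where SHP is the student's ordinary softmax output, SSP its
temperature-softened output and TSL the frozen teacher's soft labels.
Design points that were genuinely open:

* The hard-label argument of the mixed loss is taken as the student's
  T = 1 output, the standard distillation reading.
* KL direction is KL(teacher || student), the standard distillation form.
* The attention-pass term, read literally, scores the frozen teacher's
  prediction on the AttentionPicture and therefore carries no student
  gradient. The default instead scores the **student** on the teacher's
  AttentionPicture, so the term trains the student;
  `distill_params(literal_attention_term = TRUE)` restores the literal form.
* Mix weight `a = 0.7` and temperature `T = 4` are package defaults (no
  values are prescribed); both are exposed in `distill_params`.

## Training loops

The teacher optimizes the BACM two-pass focal loss; the student the total
distillation loss; a plain supervised baseline with an identical budget is
provided for comparisons. The optimizer is Adam, the conventional choice at small learning rates
(the method family does not mandate one). The learning rate follows
cosine annealing with restarts:

$$\eta(s) = \eta_{min} + \tfrac12(\eta_{base}-\eta_{min})
  \left(1 + \cos \pi \tfrac{s \bmod T_{max}}{T_{max}}\right),$$

reaching `eta_min` exactly at multiples of `T_max` and restarting near
`base_lr` on the next step. Every run records its per-step trace, which the
tests compare with this closed form. Reference protocol values (50 epochs,
batch 8, learning rate 1e-5) are the `train_config()` defaults; miniature
runs use 1e-3, which is appropriate for the much smaller widths. Model
selection keeps the best-validation-accuracy epoch, ties to the earlier
epoch. Validation always runs in evaluation mode with augmentation disabled.
Checkpoints round-trip through RDS with a JSON sidecar of the model
configuration; resuming mid-run is not supported (a fresh run under the same
seed reproduces the history instead).

## Augmentation

Batch augmentation composes, per tile and in a fixed listing order, a random
subset of: random flip, random rotation, horizontal/vertical flip,
saturation jitter, Gaussian noise, contour extraction and smoothing — each
included with probability 0.5 by default, deterministic under the batch
seed, never persisted to disk, and never touching labels or masks. Two
operators admit several reasonable definitions and are therefore
configurable: "extract
the outline" is implemented as a Sobel edge-magnitude map blended with the
source (weight 0.5), preserving the three-channel contract; rotation uses
reflection padding with an exact 90-degree mode for tests.

## Synthetic slides

The generator stands in for the private slide archive; no real data ships
with the package. Each slide is a filtered-noise texture field: a per-class
RGB tint (an H&E-like palette — pale eosin pink for normal tissue, a
basophilic purple, a lipid-rich ochre, a dark melanotic brown) plus Gaussian
noise smoothed at a class-specific spatial scale (sigma 1, 2, 4, 8 px), so
classes differ in both color balance and texture scale, the two cues a
patch classifier would use on real stains. Tumor slides carve a lesion —
a rectangle (exact-area mode for arithmetic tests) or a thresholded smooth
noise blob — whose area fraction is drawn from `lesion_fraction_range`, and
fill it with the class texture; the mask is 1 exactly there. Everything is
deterministic given the seed, and pixels are quantized to 8-bit levels.

What the generator does **not** emulate: stain variability and artifacts,
nuclear morphology, tissue boundaries, scanner pyramids, or any spatial
correlation between lesion shape and class. Passing the miniature
experiments therefore demonstrates that the pipeline's mechanics — tiling,
attention cropping, distillation, reassembly — operate and learn correctly,
not that the architecture reaches clinical accuracy on real slides.

## Miniature experiment sizes

The seeded end-to-end checks (also recomputed by `scripts/acceptance.R`)
use: 256-px slides, 10 per class, rectangular lesions covering 35–65% of the
slide; 64-px patches at stride 16 under the strict 3/4 rule, 200 training
patches per class (800 total) and 240 held-out patches; a width-1/16,
two-blocks-per-stage teacher trained 5 epochs with BACM (batch 8, Adam,
base_lr 1e-3, cosine annealing); student arms trained 3 epochs from the
same data, distilled (`a = 0.7`, `T = 4`) versus identically budgeted plain
supervision over 3 seeds; per-class U-Nets (width 4, depth 2) trained 3
epochs on 200 lesion tiles; and 12 fresh slides (3 per class) for the
slide-level pipeline. Under these conditions the miniature teacher exceeds
95% held-out patch accuracy, the distilled student matches or exceeds the
plain baseline on average, and the reassembled lesion masks exceed 0.5 IoU
against ground truth.

## Slide-level inference

At inference no mask exists, so *every* window is classified. The
slide-level call is a majority vote over non-normal patch calls (an
all-normal slide is called normal; ties break toward the class with the
higher mean probability) — the aggregation arithmetic is a package choice;
only the stages themselves are fixed by the method. Tumor-called patches
are segmented by the called class's U-Net; overlapping probabilities are
averaged per pixel (accumulate/count, verified against a brute-force oracle)
and thresholded at 0.5. Edge pixels covered by no full window remain 0 and
are flagged. Attention heatmaps place each window's normalized selected
attention map at its origin, averaging overlaps, and render a red-tinted
overlay.

## Known limitations

* The engine is CPU-only and single-threaded R + BLAS; it is built for
  correctness and desk-scale experiments, not for full-resolution training.
* The attention head receives no gradient (the crop geometry is
  non-differentiable and the head only steers cropping), matching the
  role of random attention selection in crop-based augmentation; richer
  attention supervision (e.g. bilinear attention pooling) is out of scope.
* `jpeg-q95` appears in the codec interface for completeness but only PNG
  encoding is available; the size-filter threshold is calibrated for PNG.
* Masks are binary; multi-class lesions within one slide are not modeled.
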