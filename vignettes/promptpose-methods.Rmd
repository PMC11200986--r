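---
title: "Language-image contrastive pose estimation with dynamic conditional prompts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Language-image contrastive pose estimation with dynamic conditional prompts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Top-down animal pose estimation takes an image and a per-instance bounding
box and returns M named keypoints (nose, left elbow, ...) as (x, y)
coordinates with visibility flags. Image-only estimators struggle when
training data are scarce and appearance varies wildly across species;
language carries stable prior knowledge about what a "left front paw" is.
`promptpose` implements a language-image training scheme in which every
keypoint owns a natural-language prompt, and text and image features are
aligned contrastively while a conventional heatmap head does the actual
localization.

The moving parts, for one instance crop:

1. **Prompt construction.** Each keypoint name is inserted into one sentence
   template (templates come in prefix, intermediate and suffix forms,
   depending on where the name sits). In front of the embedded sentence
   tokens sit `q` learnable context vectors `V_1 ... V_q` (default `q = 8`;
   shorter contexts carry too little information and much longer ones
   dilute it, so a moderate length is the standard choice). A
   meta-network `g` -- two affine layers with a ReLU bottleneck -- maps the
   globally pooled projected image feature to a single conditional token
   `alpha = g(pool(I_p))`, and every context vector is shifted by it:
   `V_i(I_p) = V_i + alpha`. The shift is shared by all M keypoints of one
   image, so prompts are *dynamic*: each image sees its own version of the
   same learned context.
2. **Encoding.** A small vision transformer turns the crop into an
   `H x W x D_I` feature map `I`; a per-cell affine projection aligns it to
   the text width (`I_p`, `H x W x D`). The prompt sequences run through a
   small text transformer and are pooled at their final token into
   `P_raw` (M x D); single-head residual self-attention over the M rows
   (`P_prompt = P_raw + Attn(P_raw)`) lets related keypoints (nose and eyes,
   say) share semantic evidence.
3. **Matching.** `Q[m, n]` is the cosine between prompt `m` and the local
   image feature of keypoint `n` (a 3x3 bilinear neighborhood average around
   the ground-truth location, spacing one feature cell). `S[m, i, j]` is the
   cosine between prompt `m` and cell `(i, j)` of `I_p` -- a text-conditioned
   probability landscape over the crop.
4. **Prediction.** The heatmap head concatenates `I` with the M channels of
   `S` and applies a per-cell two-layer network whose output layer emits a
   2x2 block per grid cell -- a stride-2 transposed convolution producing
   per-keypoint heatmaps at twice the feature resolution. Decoding takes the
   argmax cell plus a quarter-cell shift toward the larger axis neighbor.

Training minimizes, per instance,

```
L = L_heatmap + beta * L_match + beta * L_spatial,      beta = 2,
```

where `L_heatmap` is per-keypoint summed squared error against unit-peak
Gaussian target heatmaps, `L_match` is the symmetric cross-entropy between
the row-softmaxed `Q` (and its transpose) and the diagonal assignment, and
`L_spatial` is the same squared-error form between `S` and Gaussian spatial
targets `S_t`. All three terms are restricted to labeled keypoints
(v > 0) and normalized by the labeled count.

Evaluation follows the Object Keypoint Similarity protocol:

```
OKS = sum_i exp(-d_i^2 / (2 s^2 k_i^2)) [v_i > 0] / sum_i [v_i > 0]
```

with `s = sqrt(instance area)`; AP at threshold T is the fraction of
instances with OKS strictly above T, AP averages the grid 0.50, 0.55, ...,
0.95, AP50/AP75 are the single-threshold values, and APM/APL restrict to
medium (32^2 <= area <= 96^2) and large (area > 96^2) instances.

## Design choices where the method description is open

Several components are named but not pinned down by the method description;
the package makes each one explicit configuration:

- **Matching temperature.** Cross-entropy directly on cosines (range
  [-1, 1]) saturates poorly, so the logits are scaled by a learnable inverse
  temperature initialized at 1/0.07, the standard contrastive-learning
  value. Setting `temp_learnable = FALSE` and `temp_init = 1` recovers the
  literal cross-entropy-on-cosines reading.
- **Spatial targets `S_t`.** Chosen as per-keypoint 2-D Gaussians in
  feature-cell units, peak-scaled to 1 so they live on the cosine scale;
  width `sigma_s = 1` cell.
- **Target heatmaps.** Unit-peak Gaussians with `sigma_h = 2` heatmap
  cells, the common choice in heatmap regression; heatmaps live at twice
  the feature-grid resolution via the 2x2-block output layer.
- **OKS weights `k_i`.** The protocol requires per-keypoint weights but published
  OKS evaluations rarely state their values; the package uses a single
  configurable constant (default 0.1) replicated per keypoint, overridable
  per schema. Reported numbers are therefore internally consistent rather
  than claimed identical to any published evaluation.
- **Meta-network width.** "Non-linear, fully connected" is implemented as
  D -> max(4, D/16) -> e with ReLU, following the conditional-prompt
  literature's bottleneck design.
- **Residual attention head count.** Single-head; the mechanism is a
  residual update, so zeroing the value projection recovers the identity
  exactly (a property the tests rely on).
- **Template inventory.** Three templates per form, written for this
  package and fully replaceable from YAML; one template is drawn per
  keypoint per run (uniformly over the pooled inventory, seeded), not per
  batch, keeping text targets stable during training.
- **Visibility handling.** v = 0 keypoints are excluded from every loss
  term and their normalizers; v = 1 (labeled, occluded) keypoints
  participate normally, as the annotation still certifies the location.

## Encoders and the autodiff tape

No deep-learning framework is involved: the encoders are small pre-norm
transformers (default: one block each, width 32, patch size 4 on 64 px
crops) written directly on a minimal reverse-mode autodiff tape that ships
with the package. The tape covers exactly the operations the model needs
(affine maps, layer norm, softmax rows, matmul, gather, normalization,
masked squared error, diagonal cross-entropy), and every gradient is
verified against central finite differences in the test suite. This keeps
the entire pipeline trainable end to end -- context vectors, meta-network,
encoders, projection, attention, head and temperature all receive exact
gradients -- at sizes where a desk CPU trains in about a minute. Nothing in
the package attempts to reproduce any pretrained encoder's numerics; an
external language-image backbone would slot in behind the same interfaces.

## The synthetic data generator

Real animal-pose corpora require large downloads, so the package generates
its own study conditions: stick-figure quadrupeds with a canonical joint
layout per schema, jittered per instance by rotation and pose noise, scaled
to exact target areas, and rendered with one distinct marker color per
keypoint over a low-frequency textured background. Annotations are the
generator's own coordinates, so ground truth is exact by construction and a
perfect predictor has zero localization error. Instance scale classes are
drawn to match the configured medium/large mix against the 32^2/96^2 area
partition; occluded keypoints (v = 1) are drawn and then covered by a gray
patch; unlabeled ones (v = 0) are omitted and zeroed. Generation is a pure
function of the seed, with one counter-derived RNG substream per image, so
datasets are byte-reproducible.

What the generator deliberately does not emulate: photo-realistic texture,
species-level appearance variation, perspective foreshortening, or
ambiguous symmetric limbs. Its distinct marker colors make localization
*learnable by the image branch alone* -- which is precisely what makes the
fast desk-scale smoke tests possible, but also means that passing them
demonstrates that the machinery optimizes and localizes correctly, not that
language supervision is necessary for this toy task (on real data the image
cue is nowhere near this clean).

## Problem sizes and numerical choices

The package's test and demonstration runs use the desk-scale profile chosen
once for this artifact: 64 px single-instance crops, width-32 encoders,
64 training images, minibatch 4, learning rate 3e-3, at most 200 optimizer
steps (the full-scale training schedule -- AdamW, lr 1e-4, weight decay 1e-4,
batch 32, 210 epochs with factor-10 decays at epochs 170 and 200 -- remains the
config default and is exercised analytically through the schedule
arithmetic). Under that profile the full model reaches an OKS AP above 90
on its training fixtures within 200 steps. The ablation comparison trains
the heatmap-only baseline and the full model on paired seeds to effective
convergence (32 images, 600 steps, factor-10 decays at epochs 60 and 70 of
75) and compares median AP; at shorter budgets the auxiliary losses slow
heatmap convergence on this image-sufficient task, so the directional
comparison is meaningful only once both variants have plateaued.

Degenerate inputs are handled explicitly: zero-norm rows are a hard error
in cosine computations (and epsilon-smoothed only inside the training
graph); all-zero heatmaps decode to score 0 with v = 0; argmax ties break
toward the smallest (row, col); an empty medium or large partition reports
NaN rather than a number; OKS with no labeled keypoint is an error, and
such instances are skipped during dataset evaluation.

## Known limitations

- The per-instance AP definition (fraction of instances whose OKS exceeds
  each threshold, averaged over the grid) is the printed protocol
  implemented here; the full COCO evaluator additionally ranks by score
  across instances and interpolates a precision-recall curve, so numbers
  are not interchangeable with COCO-toolkit output. In the per-instance
  matched setting AR coincides with AP by construction.
- Matching negatives span the M keypoints within one instance, not a
  batch; hard-negative mining is out of scope.
- One prediction per ground-truth box (no detection stage, no flip-test
  averaging, no multi-scale augmentation).
- On the synthetic task the language branch is auxiliary rather than
  necessary, so ablation effects are small and can run in either direction
  at tight step budgets; the package therefore makes only a directional,
  convergence-budget claim about them (see the acceptance tests), not a
  magnitude claim.
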