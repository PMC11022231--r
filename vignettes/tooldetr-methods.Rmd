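---
title: "Set-prediction detection of surgical instruments: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Set-prediction detection of surgical instruments: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Laparoscopic video frames contain a small, variable number of elongated
metallic instruments seen at wildly different scales, often partially
occluded and surrounded by specular highlights. `tooldetr` implements an
anchor-free detector for this setting: instead of scoring a dense grid of
candidate boxes, the model emits a fixed set of `Q` *object
representations* and lets a bipartite matching decide which representation
is responsible for which annotated instrument.

The pipeline is:

1. **Multi-scale backbone.** A convolutional backbone with
   hierarchical-residual blocks: the channels of each block are split into
   `scale_groups` groups of `group_width` channels; group 1 passes through,
   and each later group is convolved after receiving the previous group's
   transformed output, so groups see increasingly large receptive fields
   within a single block. The full variant uses four groups of 26 channels
   in a 50-layer four-stage layout with feature taps after stages 2 and 4
   (strides 8 and 32). Two feature maps at different resolutions are
   tapped.
2. **Projection and positional encoding.** Each tap goes through its own
   1x1 convolution down to a common width `d` (256 in the full model). The
   position of a cell on its `h_s x w_s` grid is mapped to a phase
   `4*pi * x / w_s` (and `4*pi * y / h_s` for the second channel band), so
   cells at the same *relative* image location receive the same phase on
   both grids — this is what lets the encoder attend jointly across scales.
   The phase is expanded into a geometric-frequency sine/cosine stack over
   its channel band.
3. **Transformer.** The flattened, position-encoded, scale-concatenated
   token sequence passes through a transformer encoder; a decoder turns `Q`
   zero-initialized content queries (each with a learned positional
   embedding) into `Q` object representations. A one-layer softmax head
   predicts `C` foreground classes plus a no-object class; a 3-layer MLP
   with a sigmoid predicts normalized `(cx, cy, w, h)` boxes.
4. **Losses.** Ground truth is padded with no-object entries to length `Q`
   and matched 1:1 to the predictions by the Hungarian algorithm on the
   cost `L_box + lambda3 * (1 - p_hat(c_i))`, with
   `L_box = lambda1 * L1 + lambda2 * (1 - GIoU)`. The *Hungarian loss* then
   sums, over the matched pairs, cross-entropy on all rows (no-object rows
   down-weighted by `eos_coef`) plus the box loss on real rows. A
   *supervised contrastive loss* reuses the matching: for every class in
   the batch, the matched representations of that class form positive
   pairs (all unordered pairs; a lone representation is paired with
   itself), everything else matched in the batch forms negatives, and a
   normalized-temperature cross-entropy on cosine similarities pulls
   classes together and apart. The joint objective is
   `lambda4/bs * sum_k L_H + lambda4/nc * sum_c L_CL`.

Because no deep-learning framework is available in this stack, the entire
network is differentiated by the package's own tape-based reverse-mode
autodiff engine (`R/autodiff.R`): values are plain matrices, convolutions
are im2col + GEMM, and each operation records a closure that applies the
chain rule. The engine is validated against finite differences down to the
full model (see `test-autodiff.R`).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `num_queries` | 32 (full), 16 (tiny) | decoder slots; an upper bound on objects per image |
| `embed_dim` | 256 (full), 64 (tiny) | common embedding width after projection |
| `lambda1, lambda2, lambda3` | 5, 2, 1 | L1 / GIoU / classification weights. The source work does not print its values; these are the published weights of the reference set-prediction detector family and are configurable. |
| `lambda4` | 1 | overall loss scale; both terms are equally weighted |
| `eos_coef` | 0.1 | no-object down-weighting in the cross-entropy. With 16–32 queries and at most 3 objects the no-object rows would otherwise dominate; set to 1 for the literal unweighted sum. |
| `temperature` | 1 | contrastive softmax temperature (the literal form of the loss) |
| `range_constant` | `4*pi` | positional phase at the far image edge (two sinusoid periods) |
| learning rate | 1e-4, x0.5 / 40 epochs, floor 1e-6 | the published step schedule |
| patience / min_delta | 50 / 1e-5 | early stopping on validation loss |

## Design choices where the design was open

* **GIoU sign.** The box loss is written in the source as *adding* the
  GIoU; a loss must penalize poor overlap, so the package uses
  `1 - GIoU` (the convention of the detector family this architecture
  extends). A `giou_mode = "literal"` switch preserves the printed form
  for audit; minimizing it drives boxes apart.
* **Cross-entropy form.** The printed set loss carries a stray factor of
  the class index multiplying the log term; multiplying a loss by a class
  *index* is unit-inconsistent and would zero out class 0, so standard
  cross-entropy is used, with the no-object down-weighting exposed as
  `eos_coef`.
* **Channel bands.** The printed phase formula splits 256 channels as
  [0,152] / [153,255] while the accompanying figure says "first and second
  half". Equal halves are the default (self-consistent for any `d`); the
  153/103 split is available as `split = "legacy153"`.
* **Zero queries.** "A matrix of zeros as the query" is implemented as
  zero content queries plus learned per-query positional embeddings.
  Literal all-zero queries make every decoder slot identical — the package
  proves this collapse in a test — so they are almost surely not intended,
  but `learned_query_embed = FALSE` provides them.
* **Contrastive negatives.** The pair-building algorithm's inner loop
  ranges over *all* padded ground-truth rows, so representations matched
  to no-object rows act as negatives by default
  (`negatives = "all"`); `"foreground"` restricts them.
* **Padded cost rows.** Ground-truth padding rows enter the square cost
  matrix as constant 0. Any constant works: a constant row cannot change
  which columns the real rows take (asserted against rectangular
  assignment in `test-matching.R`).
* **(1 - p) vs -p matching cost.** The printed matching cost uses
  `1 - p_hat`; the reference family uses `-p_hat`. They differ by a
  row-constant, hence give identical assignments — asserted in a test, and
  the printed form is implemented.
* **Evaluation ranking.** AP is a ranking metric, so `evaluate_model()`
  scores *every* query as a detection for its most probable foreground
  class and lets the precision–recall ranking absorb low-confidence
  outputs; no score threshold is applied inside evaluation. The
  argmax-not-no-object + threshold rule lives only in `postprocess()` /
  `predict()`, the inference path.
* **Numeric safety.** Log arguments are clamped at `1e-12`; GIoU
  denominators at `1e-12`; layer norm uses `eps = 1e-5`. Matching is
  computed on detached values (the assignment is piecewise constant in the
  parameters, so this is the exact subgradient almost everywhere).

## The synthetic data and what it does (not) show

The published benchmark dataset is a 2,532-frame cholecystectomy
collection with seven instrument classes; reproducing its numbers needs
GPU-scale training and is out of scope here. The package instead ships a
generator that emulates the *statistical structure* the detector must
handle: frames with 0–3 instruments, long-tailed class frequencies
(default 0.35/0.22/0.15/0.10/0.08/0.06/0.04), instrument lengths from 25%
to 70% of the image side, partial occlusion by overlap (probability 0.3),
and specular speckle noise on a tissue-colored background. Each class has
a distinct tip geometry (jaws, parallel prongs, hook arc, crossing blades,
wedge, blunt tube, ring) and a distinct muted albedo, standing in for the
visual differences between real instrument types.

Annotations are exact: each object's box is the tight bounding box of its
own rendered mask. Passing tests on these scenes demonstrates that the
architecture, losses and training loop *work end to end* — they do not
demonstrate clinical-grade accuracy on real video, where texture,
motion blur, smoke and lighting are far richer than this renderer.

## Desk-scale training protocol

All training in the test suite and the acceptance script runs on one CPU,
so problem sizes are chosen accordingly: the `tiny` configuration
(two-stage backbone with strides 4/8 and group width 8, `d = 64`, 1
encoder + 2 decoder layers, 2 heads, 16 queries) on 64x64 scenes with 5
classes, 200 scenes (70/30 train/validation), 30 epochs. Several choices
depart from the published large-scale protocol, for the same reason the
tiny model exists at all:

* **Learning rate 5e-4, batch size 2, gradient clipping off.** The
  published schedule (1e-4, hundreds of epochs) is built for a large model
  trained for ~10^5 steps. At desk scale the budget is ~10^3 steps, and a
  validation sweep at that budget favours a larger rate with more, smaller
  steps; the global-norm clip at its conventional value throttles every
  component of this small model's gradient, so the desk protocol disables
  it (`clip_norm = 0`). The schedule machinery itself (step decay, floor,
  early stopping) is unchanged.
* **Attention gain 2 (`tiny_detector_config()` default).** At `d = 64`
  the attention logits start near zero and attention is almost uniform
  over the 320 tokens; instrumented runs show it stays diffuse for most of
  a desk budget. Doubling the logit scale lets attention commit to tokens
  early; with the anchor-grid query initialization (see
  `?detector_init`), cross-attention measurably localizes within ~15
  epochs.
* **Unweighted no-object cross-entropy (`eos_coef = 1`).** The class term
  is used exactly as written, without the conventional down-weighting of
  no-object rows; the weight remains configurable.
* **Augmentation off for the desk runs.** The 33%-per-transform protocol
  is implemented and tested as a module; at 10^3 steps on synthetic scenes
  whose train and validation splits are i.i.d. from the same renderer,
  augmentation only slows convergence, so the desk protocol disables it.

### What desk-scale training does and does not achieve

A set-prediction detector trained from random initialization is known to
converge slowly even at full scale; in ~10^3 CPU steps the desk runs reach
what can be called the *content-blind floor* of the objective. Decomposing
the loss before and after a 30-epoch run (per validation image, eos = 1):

| term | init | after 30 epochs | floor interpretation |
|------|------|-----------------|----------------------|
| class CE | 13.5 | 8.0 | marginal class/no-object prior |
| L1 box   | 6.5  | 3.0 | static per-query "box dictionary" |
| GIoU     | 4.1  | 2.5 | same |
| contrastive (per batch) | 4.1 | 3.9 | positive floor, see below |

Every component improves, attention localizes, and the best-IoU query per
object reaches IoU >= 0.5 for a third to a half of objects — but scores
are not yet content-dependent enough to *rank* correct boxes above the
rest, so mAP50 stays in the 0.01–0.1 range rather than the publication's
range. Matching the published detection quality requires the published
compute (large backbone, ~10^5 gradient steps); the desk protocol
demonstrates correct mechanics, exact-oracle losses, and the direction of
training, not end-task accuracy.

The contrastive mechanism is visible even here: running the desk task
with the contrastive term on versus off (three seeds each, matched
epochs) shifts the median silhouette of matched object representations
from −0.170 to −0.101. Both values are negative — at this scale the
embeddings do not yet form clean class clusters — but the shift is in the
claimed direction and consistent across seeds.

The contrastive term has a positive floor at this scale: with `m`
positives and `q >> m` negatives per class its minimum is about
`log(1 + q / (|P| e^2))`, so the *total* loss cannot approach zero even
when detection is nearly perfect; loss-reduction checks in the tests are
stated relative to the initial loss with this in mind.

## Known limitations

* Pure-R training is two to three orders of magnitude slower than a GPU
  framework; the full 320x320 / `d = 256` configuration is constructible
  and runs forward passes, but training it is impractical here.
* No auxiliary per-decoder-layer losses, no dropout: the source work never
  mentions either, and at desk scale both are unnecessary.
* Nearest-neighbour warping in the augmenter can alias thin structures at
  strong rotations; boxes are transformed exactly, so annotations remain
  conservative hulls.
* The evaluator implements the 101-point interpolated AP convention; the
  source names the metric family but not the interpolation, so agreement
  with other implementations is asserted against an independently coded
  evaluator in the tests.
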