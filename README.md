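# tooldetr

Anchor-free, set-prediction detection of surgical instruments in
endoscopic images, in pure R.

Surgical scene understanding needs detectors that localize and classify
the instruments visible in each laparoscopic frame. Anchor-based
detectors bake in assumptions about object size and aspect ratio that
thin, elongated, wildly varying tools violate. `tooldetr` implements the
alternative: a transformer decodes a fixed set of *object queries* into
object representations, two feed-forward heads turn each representation
into a class (or explicit "no object") and a normalized box, and a
bipartite Hungarian matching — not anchors or non-maximum suppression —
decides which prediction owns which annotated instrument.

The model:

* a multi-scale backbone with hierarchical-residual blocks (channels split
  into groups of width 26 in the full model; each group's 3×3 convolution
  receives the previous group's output, widening the receptive field
  within a block), tapped at two resolutions;
* per-scale 1×1 projections into a common d-dimensional space, and a
  cross-scale sinusoidal positional encoding whose phase is
  `4π·x/w_s` — equal *relative* positions on the two grids get equal
  phases, so the encoder can attend across scales coherently;
* a transformer encoder–decoder (6+6 layers, 32 queries in the full
  configuration) producing object representations `ô_j`;
* the Hungarian loss
  `Σ_i −λ₃ log p̂_{h(i)}(c_i) + 1{c_i≠∅} [λ₁‖b̂−b‖₁ + λ₂(1−GIoU)]`
  on the optimal assignment `h`, plus a supervised contrastive loss: for
  each class, matched representations form positive pairs and everything
  else matched in the batch forms negatives, scored by
  `−log Σ_P e^{sim} / Σ_{P∪N} e^{sim}` with cosine similarity;
* COCO-style evaluation (per-class AP, mAP@[0.5:0.05:0.95], mAP50,
  mAP75) and embedding-separability metrics (within/between-class cosine,
  silhouette).

There is no deep-learning framework dependency: the package includes a
tape-based reverse-mode automatic-differentiation engine over base-R
matrices (convolution as im2col + GEMM, multi-head attention, layer norm),
validated against finite differences, which makes the whole detector
trainable on a CPU at desk scale. A synthetic laparoscopic scene
generator with COCO JSON I/O provides annotated data with the statistical
traits of the real task: 0–3 instruments per frame, long-tailed classes,
large scale variation, partial occlusion, specular noise.

## Worked example

```r
library(tooldetr)

gen    <- generator_config(num_classes = 5, seed = 1)
scenes <- generate_scenes(gen, 200)

fit <- tooldetr(scenes, tiny_detector_config(num_classes = 5),
                weights = loss_weights(eos_coef = 1),
                train = train_config(epochs = 30, learning_rate = 5e-4,
                                     batch_size = 2, clip_norm = 0,
                                     augment = FALSE, seed = 1))
print(fit)
ev <- evaluate_model(fit, scenes[fit$val_idx])
print(ev)
```

On one CPU this trains in about five minutes and prints (seed 1):

```
Set-prediction tool detector (tiny backbone, d = 64, Q = 16)
  trained 30 epochs on 200 scenes (60 held out); best val loss 14.6984
mAP@[0.5:0.05:0.95] 0.0027 | mAP50 0.0152 | mAP75 0.0001
per-class AP50:
class_0 class_1 class_2 class_3 class_4 
 0.0254  0.0458  0.0048  0.0000  0.0000
```

Temper expectations accordingly: five desk minutes of CPU training takes a
set-prediction detector from random weights through roughly 2,000 gradient
steps — enough for the loss to fall by about a quarter, for cross-attention
to localize, and for the best-overlapping query to reach IoU ≥ 0.5 on a
third of the held-out instruments, but nowhere near the ~10⁵ steps such
detectors need before confidence ranks good boxes above bad ones, which is
what mAP measures. The methods vignette quantifies exactly where the
remaining loss sits at this scale and why. `predict(fit, scenes)` returns
the detections themselves (image, class, score, normalized box);
`matched_representations()` plus `separability()` quantify how the
contrastive term clusters the decoder's object embeddings by class.

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/tooldetr.R synth --n-scenes 50 --image-size 64 --seed 1 --out data/
Rscript inst/cli/tooldetr.R train --config cfg.yaml
Rscript inst/cli/tooldetr.R detect --checkpoint fit.rds --images data/annotations.json --out dets.json
Rscript inst/cli/tooldetr.R eval --gt data/annotations.json --dets dets.json --num-classes 7
```

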