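---
title: "Detecting and counting wheat heads with WheatLFANet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and counting wheat heads with WheatLFANet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Counting wheat heads (spikes) in field photographs is a routine need in
phenotyping and yield estimation. Field imagery is hard for detectors: tens
of small, elongated, mutually occluding organs per image, strong lighting
and variety variation, and cluttered vegetative background. WheatLFANet is a
lightweight single-stage anchor-based detector designed so that detection
and counting remain practical on low-end hardware: about 0.72 M trainable
parameters and 4.06 GFLOPs at a 640-px input.

This package implements the network and its training and evaluation stack
from scratch on plain R arrays (C++ kernels via Rcpp/RcppArmadillo for
convolution, pooling, normalization and their gradients), together with a
synthetic canopy generator so the entire pipeline can be exercised,
trained and evaluated at desk scale with no external data.

## The model

The network has two stages.

**Feature encoding.** A stem of two overlapping stride-2 3x3 convolutions
takes the RGB image to 1/4 resolution at width C1; three encoder stages
(each a stride-2 convolution followed by a cross-stage partial layer,
CSPLayer) produce feature maps at strides 4, 8 and 16 with widths
C1/C2/C3 = 32/64/128. Every convolution block is Conv2d + batch
normalization + SiLU (`z * sigmoid(z)`). A CSPLayer splits its feature map
into two halves, runs one half through N residual bottlenecks
(1x1 reduce to `c * e`, 3x3, 3x3 restore, residual add), and concatenates
both halves plus every intermediate bottleneck output before a 1x1
projection: only part of the map flows through the heavy branch, which is
what keeps the parameter count low while preserving gradient diversity.

**Cross-stage fusion.** At stride 16 a simplified CSP
spatial-pyramid-pooling-fast block (SimCSPSPPF) stacks three cascaded
stride-1 5x5 max-pools over a convolutional branch, concatenated with a
positional 1x1 branch, enlarging the receptive field without losing
resolution; its output passes through a further CSPLayer. The decoder
upsamples this map by nearest-neighbour x2, aligns channels with a 1x1
convolution, concatenates with the stride-8 encoder output and remaps
through a CSPLayer (first prediction scale); a stride-2 convolution of that
decoded map rejoins the neck output for the second scale at stride 16.
Each scale ends in a 1x1 prediction convolution emitting
`anchors_per_scale * (5 + num_classes)` channels: box offsets, objectness
and class scores for three anchors per cell. All wheat varieties are merged
into a single class.

**Depth knobs.** The published description fixes the widths but not the
per-stage bottleneck counts. They are this implementation's tuning knobs;
the defaults — encoder (2, 2, 3), post-neck 2, decoder (2, 2), stem path
3→32→32 — were chosen once against the published complexity budget and give
721,028 trainable parameters (prints as 0.72 M) and 4.06 GFLOPs at 640x640
under the 2-operations-per-multiply-accumulate convention, counting
convolution layers only. A stem path through C1/2 = 16 channels cannot
reach that budget with any depth combination in the 1-3 range, which is why
the first stem convolution goes directly to C1.

## Assignment and loss

Each ground-truth box is assigned exactly one positive anchor: the one with
maximal IoU over all scales, cells and anchor shapes (ties resolved by
lowest scale, row, column, anchor index). The total loss is the published
weighted sum

L = 0.05 * L_loc + 0.7 * L_obj + 0.3 * L_cls.

* **Localization** is a complete-IoU loss,
  `1 - (IoU - rho^2 / c^2 - alpha * v)`, combining overlap, center distance
  (relative to the enclosing-box diagonal `c`) and the aspect term
  `v = (4 / pi^2) (atan(w_g / h_g) - atan(w / h))^2` with weight
  `alpha = v / ((1 - IoU) + v)` treated as a constant during
  differentiation. Predictions are decoded to boxes before the loss, so it
  operates in box space.
* **Objectness and classification** use binary cross-entropy weighted by a
  missing-label attenuation factor `alpha(x) = 1 - exp((x - 1) / (a + e))`
  with `x` the prediction-minus-label difference (defaults `a = 0.25`,
  `e = 1e-8`). A confident positive prediction against a 0 label — the
  signature of an unannotated head — receives weight near 0 and stops
  penalizing the model. The factor is treated as a constant weight in the
  gradient, as is common for modulated cross-entropy losses. Note the
  factor *decreases* towards 0 as `x` rises to 1; we implement that
  printed behaviour directly.

**Normalization.** How each component is averaged is not part of the
published description, and it decides whether a short schedule can learn at
all. This package uses: objectness summed over *all* anchors and divided by
the number of positives (the dense-detector convention — with a plain mean
over the ~10^4 anchors per image, the per-positive gradient is ~1e-5 and
objectness never lifts off its prior in a few hundred steps); localization
summed over positives and divided by the batch size (the historical
single-stage convention — a per-positive mean under the small 0.05 weight
leaves box gradients ~100x weaker than objectness gradients and the boxes
never fit); classification averaged over positives. Both choices were
verified on small probes where the alternatives demonstrably stall.

## Post-processing and evaluation

Raw head outputs decode per cell and anchor as
`center = (2 * sigmoid(t) - 0.5 + cell) * stride` and
`size = anchor * (2 * sigmoid(t))^2` — bounded transforms whose exact
inverse is used for encoding. Class-agnostic greedy NMS (IoU threshold
0.45; confidence floor 0.25 for detection output, 0.001 when evaluating)
removes duplicates.

Evaluation reports precision, recall and F1 at the operating confidence,
average precision at matching IoU 0.5 (confidence sweep, precision
envelope, all-points integration), the area of the F1-versus-confidence
curve, and the counting metrics MAE, RMSE, MAPE (zero-count images
excluded and flagged) and R^2 computed with the standard total sum of
squares `sum((G - mean(G))^2)` in the denominator.

## The synthetic generator

`scene_config()` / `render_scene()` emulate what makes field imagery hard,
not its photometric detail: a low-frequency green-brown canopy with
clutter noise; heads as oriented Gaussian-textured ellipses (banded
spikelet texture, stochastic awn strokes, lengths 10-60 px at 640-px
scale, aspect ratios 1.5-3.5); overlapping placement with per-pixel
ownership so every ground-truth box is the tight bound of the *visible*
extent (heads occluded beyond 90% are dropped); global gain/gamma jitter
and Gaussian blur. Per-image instance counts follow a negative binomial
with mean 42 and dispersion 0.71 — the dispersion is the one-time
calibration at which the theoretical median crosses 24, reproducing the
strongly right-skewed per-image counts of large field datasets (median
well below the mean).

The "easy" preset (no occlusion, high contrast, little clutter or blur) is
the substrate for desk-scale training checks. Two of its aspects deserve
emphasis. First, it keeps head sizes at field scale (10-60 actual pixels)
regardless of render size: a 320-px render would otherwise contain 2-5-px
heads below what a stride-8 grid can resolve. Second, passing tests on
easy scenes demonstrates that the implementation can learn — gradients,
assignment, decoding and evaluation are consistent — not that the network
reaches its published field accuracy; real canopies have occlusion
patterns, variety differences and backgrounds the generator does not
model.

## Training

`train_network()` is plain SGD with momentum 0.937, weight decay 5e-4 on
convolution kernels only, batch size 8 and a cosine learning-rate schedule
from 0.01 to 1% of that over 100 epochs at 640-px input — the published
full-scale regime. No warmup, EMA, augmentation or pretrained weights are
used. Validation precision/recall/AP are computed each epoch and the
best-AP weights (including BN running statistics) are restored at the end.

`desk_preset()` is the scaled-down configuration used by the package's
end-to-end check: quarter widths (16/32/64), 320-px input, 200 easy
synthetic scenes, 50 held-out scenes, 15 epochs, anchors re-estimated from
the training boxes by k-means. Its schedule uses batch size 4 and initial
learning rate 0.03: half the batch doubles the number of SGD steps at
identical cost, and the hotter start compensates a schedule ~100x shorter
than the field regime (pilot runs showed rates of 0.05 and above degrade
counting R^2). On one CPU the preset trains in under ten minutes and
reaches held-out AP ≈ 0.86 and counting R^2 ≈ 0.98 (seed 0) — the
acceptance suite asserts the weaker bounds AP ≥ 0.5 and R^2 ≥ 0.5.

## Numerical choices

* BN uses `eps = 1e-3` inside the square root, biased batch variance, and
  running statistics updated with rate 0.03; convolutions under BN carry no
  bias. Conv/BN fusion folds `W' = W * gamma / sqrt(var + eps)`,
  `b' = beta - mean * gamma / sqrt(var + eps)` and preserves outputs to
  ~1e-12 relative.
* The activation kernels use a range-reduced polynomial `exp`
  (relative error ~1e-7, well inside the 1e-5 oracle tolerance the tests
  enforce); everything else is double-precision libm.
* Head objectness biases start at logit(0.01) so the untrained network
  predicts sparse foreground.
* Degenerate geometry: IoU of two zero-area boxes is 0; assignment
  tie-breaks are lexicographic; NMS ties keep the earlier (higher-ranked)
  detection; MAPE skips zero-count images.
* Weight initialization is uniform Kaiming-style; all randomness (weights,
  scene generation, shuffling, k-means) flows from caller-supplied seeds.

## Known limitations

* The prediction heads sit at strides 8 and 16 only; heads smaller than
  ~6 px or larger than ~200 px at network resolution are outside the
  anchor range the defaults cover.
* The implementation is CPU-only and double-precision; it is built for
  correctness and desk-scale experiments, not for the real-time inference
  rates the architecture achieves in optimized deployments.
* Published field-accuracy figures (AP 0.900, R^2 0.949 on the external
  multi-site dataset) require that dataset and GPU-scale training; nothing
  in this package claims to reproduce them, and the test suite computes
  only the quantities it can verify end to end at desk scale.
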