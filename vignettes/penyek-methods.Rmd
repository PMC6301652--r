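---
title: "Methods: classifying imperfect planthoppers from sticky-pad imagery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying imperfect planthoppers from sticky-pad imagery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(penyek)
```

## The problem

The brown planthopper (BPH, *Nilaparvata lugens*) is the most destructive
pest of rice across east and south-east Asia; monitoring its abundance is a
prerequisite for targeted pesticide use.  A cheap field protocol traps
hoppers on glue-coated plates ("sticky pads") which are then photographed.
The catch: specimens on a pad are *imperfect* — flattened by the impact,
decayed, or missing body parts — so classifiers trained on intact museum
specimens transfer poorly, and colour is unreliable under field
illumination.

This package implements a pipeline built around a shape-robust
representation.  Each annotated circular patch is binarized, the binary
silhouette is transformed by one of seven *image models*, and the result is
fed to a compact convolutional network (CNN) or to hand-crafted-feature
baselines:

| model | input to the classifier |
|-------|-------------------------|
| A | 1-px inner outline of the silhouette |
| B | silhouette with enclosed holes filled |
| C | topological skeleton (thinning) |
| D | watershed-separated silhouette |
| E | Voronoi tessellation lines between components |
| F | Euclidean distance map (EDM), rescaled to 8 bits |
| G | the raw RGB patch, no transform |

Model F — the distance map — is the pipeline's centrepiece: the EDM value
at a pixel is its exact Euclidean distance to the nearest background pixel,
so the representation encodes body thickness smoothly and degrades
gracefully when outline details are torn away.

## Binarization chain

1. **Grayscale** — ITU-R BT.601 luma, $0.299R + 0.587G + 0.114B$, rounded
   half-up.  (The source work states only that images are converted to
   grayscale; 601 weights are the conventional choice for 8-bit imagery.)
2. **Median filter** — 3×3 window by default, edge-replicated borders.
3. **Iterative two-threshold split** — the intensity histogram is divided
   into three classes (dark insect, mid clutter, pale pad) by maximizing
   the three-class between-class variance
   $\sigma_B^2(t_1,t_2)=\sum_k w_k(\mu_k-\mu)^2$.  The optimizer is
   coordinate ascent: with one threshold fixed, re-placing the other at the
   two-class optimum of its sub-histogram is exactly the coordinate-wise
   maximizer, so the objective is monotone along an ascent and terminates
   (tolerance 0, cap 100 iterations).
4. **Morphological closing then opening** — disk element, radius 1
   (rasterized with half-pixel inflation, so radius 1 is the 3×3 box and
   axis-aligned rectangles are fixed points).
5. **Size filter** — components below 30 px (at the synthetic scale) are
   removed; 8-connectivity throughout.

Foreground polarity defaults to *darkest class* — insects are darker than
the pad — and is configurable, as is every parameter above.

### Why multi-start coordinate ascent

Single-start ascent from the tercile boundaries stalls in a local optimum
on roughly one in ten flat (noise-like) histograms.  Since the method's
contract is agreement with the exhaustive-search optimum (ties allowed) on
at least 95% of random images, the implementation restarts the ascent from
a small deterministic quantile grid (terciles plus all pairs drawn from
deciles {10, 25, 40, 50, 60, 75, 90}) and keeps the best stationary pair.
Each start costs a handful of vectorized histogram scans; the worst
observed disagreement rate drops to ~1%.  The mechanism is still iterative
coordinate ascent — exhaustive search remains the *test oracle only*, so
the dual-route check stays meaningful.

### Degenerate histograms

Fewer than three distinct intensity levels make a two-threshold split
meaningless; `iterative_multithreshold()` errors and the chain falls back
to the classical two-class variance threshold.  An all-foreground mask has
no defined distance map; `euclidean_distance_map()` refuses it rather than
inventing infinities.

## Binary transforms

* **EDM** — exact, via the per-dimension lower-envelope (parabola)
  algorithm; verified against a brute-force minimum-over-background oracle
  to 1e-9 on random masks.  Rescaling to 8 bits maps 0 to 0 and the
  per-image maximum to 255 (half-up rounding), so the dynamic range is
  always fully used.
* **Skeleton** — Zhang–Suen thinning with one correction: candidates are
  marked from the frozen image per the classic two-subiteration rules but
  deleted *sequentially* under a simple-point guard (crossing number 1, at
  least two neighbours in the current image).  The textbook parallel
  deletion annihilates isolated 2×2 blocks, which would change the
  component count — a property the test suite pins.
* **Watershed separation** — the foreground EDM is flooded downhill from
  its regional maxima; basins whose peak rises less than 0.5 distance
  units above a saddle merge (plateau tolerance against over-segmentation),
  all other saddle pixels become ridge pixels and are removed.
* **Voronoi lines** — the same flooding run on the background's
  distance-from-particles map: background pixels reached by two different
  particles form the tessellation lines.  Fewer than two components give
  an empty result by definition.

All transforms are deterministic and respect subset/superset contracts
(outline/skeleton/watershed ⊆ input, hole-filling ⊇ input, Voronoi ∩ input
= ∅) that the property tests enforce on random masks.

## Classifier layer

The convolutional engine is implemented in compiled code (im2col + GEMM)
because no deep-learning framework exists in the supported library set.
Backpropagation is hand-rolled and verified against central-difference
numerical gradients (relative error < 1e-4 in the tests; in practice
~1e-8).

* **Compact presets 1–7** — two to five same-padding convolutions
  (kernels 3–11, 16–384 feature maps), max-pooling stride 2, one or two
  hidden fully connected layers, softmax head.  The printed head width in
  the source table is 3 for a two-class task; we default to 2 classes and
  keep the printed width available (`head_classes = 3`), reading the third
  output as an unused background class.  When a preset has fewer pools
  than convolutions, pooling follows each of the first $n_{pool}-1$
  convolutions and the final one.
* **VGG16-style network** — five blocks of 3×3 convolutions
  ((64,64),(128,128),(256,256,256),(512,512,512),(512,512,512)), 2×2
  pooling between blocks ("2×2" read for the source's misprinted "22
  windows"), three fully connected layers, softmax.  The three fine-tuning
  handles are explicit: a smaller learning rate, a head truncated to two
  classes, and freezing the first $k$ blocks.  Pretrained weights are an
  optional runtime input loaded from a file — never fetched — and a
  requested-but-unreadable source is an error, not a silent random
  initialization.  All tests run the architecture at reduced input size
  (32 px) with narrow FC layers; nothing depends on ImageNet weights.
* **Training** — mini-batch SGD, momentum 0.9, constant learning rate.
  Defaults follow the published hyperparameters: batch 30, initial rate
  1e-4, softmax cross-entropy.  Weight initialization is He-uniform from a
  seeded stream; shuffle orders are drawn per epoch from the same seed, so
  a (data, config, seed) triple reproduces the loss history exactly.
* **Augmentation** — each patch emits one copy per base rotation
  {90°, 180°, 270°} (plus ±15° uniform jitter), translated by up to 10% of
  the side per axis (edge-replicated), with modes `both`,
  `rotation_only`, `translation_only`, `none` mirroring the ablation arms.
  Translation-only mode emits the same number of copies for count parity
  across arms.  Multiples of 90° rotate losslessly; other angles use
  bilinear resampling.
* **Hard-negative bootstrapping** — candidates scored by the current
  model; those with $P(\mathrm{BPH}) \ge$ threshold join the training set
  as benign and the model is retrained, for a bounded number of rounds.

## Baselines

GLCM (32 levels, offsets (0,1),(1,0),(1,1),(1,−1); contrast, correlation,
energy, homogeneity per symmetrized, normalized matrix), a Gabor bank
(4 frequencies × 6 orientations, DC-free kernels, replicate borders; mean
and variance of response magnitude), uniform rotation-invariant LBP
(radius 3, 24 points, 26 bins), and 32-bin gray/HSV/RGB histograms — each
feeding a random forest (200 trees, √d features per split, Gini).  The
forest is hand-rolled in compiled code because no random-forest package is
available in the supported set; it is fully seeded.

## Evaluation

Stratified k-fold cross-validation (per-class shuffle + round-robin, fold
counts within ±1) is the primary protocol, matching the source's "5 CV"
result tables; the fixed 70/10/20 split is available as a mode.  Metrics:
accuracy, sensitivity tp/(tp+fn), specificity tn/(tn+fp) — BPH positive —
and AUC as the Mann–Whitney rank statistic over P(BPH) with ties counted
½, cross-checked against trapezoidal ROC integration.  A metric with a
zero denominator is reported as `NA` and excluded from fold means with a
warning, never silently coerced to 0.

## The synthetic world

The original pad photographs were never deposited, so a seeded procedural
generator stands in:

* **Sprites** — planthoppers are elongated ellipsoids (aspect ≈ 2.6–3.1)
  with a narrow head capsule and two wing lobes; benign insects are
  rounder (≈ 1.1–1.35) with a ring of short appendages.  *Damage* removes
  a random angular sector (~30% of the body at full severity) and applies
  a shear proportional to severity, emulating flattened, torn specimens.
  Sprite interiors are nearly flat in intensity so that an insect forms a
  single dark histogram class — the regime the two-threshold method
  assumes.
* **Colour** — per-insect tints are drawn from overlapping class
  distributions (planthoppers trend brown, benign insects grey-green).
  The overlap is deliberate: colour alone should be informative but not
  decisive, preserving the qualitative orderings of the source (colour
  histogram baselines beat chance yet lose to the EDM+CNN arm).
* **Scene nuisances** — glue specks (50 per megapixel), a multiplicative
  linear illumination ramp with random direction (default ±10% across the
  pad, emulating the dominant stated challenge), additive Gaussian noise
  (sd 5 of 255).
* **Dataset plumbing** — one insect per mini-scene; splits are by scene
  id (no leakage) with per-class largest-remainder rounding, which at the
  published sizes (337/350 patches, 70/10/20) reproduces the published
  split counts (236/34/67 and 245/35/70) exactly.
* **Damage severity default** — the source gives no quantitative damage
  distribution; severity 0.5 is the package default, at which a trivial
  moment-based aspect-ratio feature still separates the classes (the
  generator's separability contract, ≥ 80% on 200 patches), so learning
  tests are meaningful rather than vacuous.

What a green test does **not** establish: photo-realism, multi-species
clutter, specular glue reflections, camera blur, or the absolute accuracy
levels reported on the authors' field data.  The acceptance suite pins
*mechanisms* (oracle equivalences, contracts, architecture fidelity,
ablation orderings, determinism), not headline numbers.

## Numerical choices

* Half-up rounding for all intensity quantization.
* The EDM's lower-envelope recursion uses a large finite sentinel (1e20)
  rather than IEEE infinity — infinities make the envelope comparisons
  NaN and corrupt the scan.
* Pool layers use floor semantics, $(n-k)\,\mathrm{div}\,2 + 1$; an input
  too small for a pooling kernel is an immediate, named error.
* CNN inputs are scaled to [0, 1]; probabilities come from a log-sum-exp
  stabilized softmax.
* Experiment arms derive per-fold seeds as `seed * 100 + fold`, keeping
  folds independent but the whole run reproducible.

## Known limitations

* The per-patch thresholding variant can split a large, nearly uniform
  insect instead of separating insect from pad when the patch contains
  little background; whole-image thresholding (the default in the scene
  recovery tests) is the robust mode.
* The watershed's basin-merging tolerance (0.5) is a fixed plateau guard,
  not a learned parameter; heavily overlapping insects are out of scope.
* Training at the published 224×224 VGG16 scale is supported by the
  engine but not exercised in tests (single-CPU budget); tests use the
  compact presets and a reduced VGG16.
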