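---
title: "Methods: multiclass segmentation of Wilms tumor histopathology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiclass segmentation of Wilms tumor histopathology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(renalseg)
```

## The problem

Post-chemotherapy risk stratification of Wilms tumor (nephroblastoma)
depends on quantifying the tumor's histological make-up: how much viable
blastema, stroma and epithelium remains, and how much of the lesion has been
replaced by chemotherapy-induced necrosis, bleeding and regression.
Pathologist estimates of these proportions show substantial interobserver
variation. `renalseg` implements a pixel-level classification pipeline for
H&E-stained slides that assigns each pixel to one of fifteen renal and tumor
tissue components, so that component proportions can be computed
reproducibly.

## Class taxonomy

The annotation vocabulary has 19 components; four (background, anaplasia,
adrenal medulla, adrenal cortex) are excluded from modeling for lack of
data, leaving the 15 evaluated classes with integer ids 0–14:

```{r}
tax <- build_default_taxonomy()
tax
```

Two groups — *vital tumor components* (blastema, stroma, epithelium) and
*chemotherapy-induced changes* (necrosis, bleeding, regression) — are
reported as pooled rows in every metrics table. Each class additionally
belongs to exactly one of two overarching meta-labels, *tumor* or
*non-tumor*. We implement the meta-labels as a fixed, user-overridable
partition exposed for auxiliary supervision, not as extra softmax outputs:
their original training role is not documented, and only the 15-class
softmax is needed for everything this package computes. Our partition puts
blastema, stroma, epithelium, necrosis, bleeding, regression and the
nephrogenic rest precursor lesion under *tumor* and the remaining eight
normal-tissue classes under *non-tumor*.

## Annotations, rasterization, and the case-exclusive split

Annotations are simple polygons in an ASAP-style XML dialect, in pixel
coordinates at the slide's base resolution (0.24 μm/pixel by default).
Rasterization uses a pixel-center rule: pixel (row *i*, column *j*) takes a
polygon's class when its center (*j*+0.5, *i*+0.5) falls inside the polygon
(even-odd rule); overlaps resolve to the highest annotation id ("last drawn
wins" — any fixed rule would do; this one is auditable from the file).
Pixels covered by no polygon carry a reserved *unannotated* value (255) and
are excluded from the loss and from all evaluation: annotation is sparse and
only annotated evidence is trusted.

The train/validation/test split is performed on **cases**, never on
annotations, so no case leaks between partitions. Cases are shuffled by
seed and assigned greedily to the partition with the largest remaining
annotation deficit relative to the 70/15/15 targets. Exact 70/15/15 is
generally unattainable at case granularity; the realized fractions are
recorded in the returned `split_spec` and are guaranteed within one
case-worth of the targets. With exactly three cases each partition receives
one case regardless of the fractions.

## The synthetic cohort

No public cohort of annotated Wilms tumor slides exists, so the package
ships a seeded generator that emulates the *statistical* structure the
pipeline assumes, not histology itself. Each case is an RGB image
partitioned into convex polygonal regions by a Voronoi tessellation of
random sites (we keep the cell edges straight rather than smoothing them:
the exported polygon annotations and the dense ground-truth mask are then
produced by the same rasterization and agree exactly, which the test suite
exploits). Each region draws a class from configurable frequency weights;
the first case's first fifteen regions are forced to a permutation of all
classes so per-class metrics are always defined on a cohort. Regions are
rendered from per-class texture models: a base cytoplasm/matrix color with
Gaussian noise plus elliptical "nuclei" with class-specific density, size
and anisotropy (dense small dark nuclei for blastema and lymph nodes, none
for necrosis and bleeding, sparse elongated ones for stroma and
mesenchyme). A configurable fraction of regions (default 0.7) is exported
as polygon annotations; the dense mask is kept as evaluation ground truth.

A single `difficulty` knob in [0, 1] shrinks all class color means toward
the grand mean and collapses the pairs that are genuinely confusable in real
tissue (epithelium toward blastema; mesenchyme/connective tissue and
regression toward stroma). At difficulty 0 the minimum pairwise color-mean
distance is at least 30 RGB units; at difficulty 1 the confusable pairs
essentially coincide. A per-pixel nearest-color-mean baseline classifier is
exported so the monotone degradation is itself testable.

What the generator does **not** model: stain physics, pyramid/WSI
containers, spatial correlation of textures, annotation noise, or class
boundaries that follow tissue morphology. Passing the recovery tests below
therefore demonstrates that the pipeline's machinery (sampling, training,
stitching, ensembling, scoring) is correct — not that the networks would
reach any particular accuracy on real slides.

## Patch sampling and augmentation

Training patches are sampled from annotated pixels after resampling images
to the working resolution of 0.5 μm/pixel (bilinear for pixels, nearest for
labels, half-pixel-center alignment). Class-balanced sampling is the
default: first a class present in the image is drawn uniformly, then a pixel
of that class — the standard remedy for the severe class imbalance of
sparse annotations; a flag restores plain uniform sampling. Patches are
cropped with mirror padding so border centers are valid.

The augmentation stack applies right-angle rotations and flips identically
to pixels and labels (right angles only, so labels need no interpolation),
and photometric transforms to pixels only: Gaussian blur (σ ∈ [0.5, 1.5],
p = 0.25), additive Gaussian noise (sd ∈ [0.01, 0.05] of full scale,
p = 0.25) — both are included deliberately, each with its own probability —
and HSV jitter (±0.02 hue, ±0.1 saturation/value, p = 0.5) as a minimal,
configurable reading of "color augmentation".

## Networks and training

Two families are built on the package's own RcppArmadillo engine (im2col +
GEMM convolutions with hand-derived backward passes, verified against
numeric differentiation in the test suite):

* **u-net**: encoder–decoder with skip connections and same-padding, so the
  output resolution equals the input (the original valid-padding variant
  would complicate stitching for no benefit here). Every u-net convolution
  is followed by batch normalization before its ReLU: without
  normalization, the serial encoder–decoder path trains far too slowly at
  the configured learning rate of 0.0005, while the dense-net's
  concatenation shortcuts stabilize it on their own. Batch statistics are
  used in training and exponential running statistics (momentum 0.9) at
  inference; both passes are implemented in C++ and the backward pass is
  verified against numeric differentiation in the test suite.
* **dense-net**: densely connected 3×3 blocks (each layer's input is the
  concatenation of all previous features), adapted to dense prediction with
  a 1×1 classifier head and bilinear upsampling back to input resolution.
  The classification original has no per-pixel output; the per-pixel
  ensembling this pipeline performs requires one, so the dense-prediction
  adaptation is the default.

Capacity presets: `"reference"` uses published-scale depths (u-net 4 down/4 up
at 64 base filters with two convolutions per stage; dense-net 4 blocks of 4
layers, growth 16, with compressing transitions). `"tiny"`, the desk-scale
default used by all tests, is a u-net of 2 levels at 12 base filters with a
single convolution per decoder stage, and a dense-net of 2 blocks of 2
layers at growth 8 with one pooled transition. The tiny u-net's width and
decoder depth were chosen from convergence experiments on synthetic
cohorts: 8 base filters made training a lottery across seeds (a 15-class
head over so few level-1 features occasionally loses an entire class within
a short budget), the second full-resolution decoder convolution dominated
runtime without helping accuracy, and the decoder never narrows below the
class count so the 1×1 head is not starved. Reference widths/depths were
not published; all of these are our choices.

Training follows the reference recipe: Adam, initial learning rate 0.0005,
categorical cross-entropy averaged over annotated pixels only, batch size 4
(u-net) or 16 (dense-net), with the rate halved after a validation-loss
plateau of 5 epochs ("plateau" = no strict improvement, min-delta 0,
monitored quantity = validation loss — the conventional reading). Network
inputs are centered to [-1, 1]; uncentered inputs measurably slowed early
convergence. The full budget of 200 epochs × 600 iterations is the
configured default; desk-scale runs use 10 × 50. Desk-scale patch shapes
are 96×96 for the u-net and 48×48 for the dense-net: the reference recipe
gives the u-net the larger pixel throughput per iteration (batch 4 at
412×412 versus batch 16 at 128×128), and preserving that ratio — rather
than using equal patches — proved necessary for the u-net to converge
within the scaled-down budget. The best-validation-loss weights are
checkpointed and returned (which epoch's weights were originally evaluated
is undocumented; best-validation is our choice). Training aborts with
diagnostics on non-finite loss. All randomness flows through R's RNG, so a
seeded single-threaded run is bit-reproducible.

## Inference, stitching, ensembling

Whole images are predicted by tiling: tiles of configurable size overlap by
a margin, and each pixel's probability vector is taken from the unique tile
whose *interior* contains it (interior-crop stitching). This makes the
stitched map exactly independent of tile traversal order and of the overlap
(away from a border strip as wide as the model's receptive-field edge
effects), both of which are property-tested with stub models. Overlap
averaging is deliberately not the default — it couples the output to the
tiling. The two networks are combined by per-pixel arithmetic averaging of
their softmax outputs; means of simplex vectors stay on the simplex. Label
maps come from the per-pixel arg-max with ties broken toward the lowest
class id.

## Evaluation

All scores derive from a single 15×15 pixel confusion matrix over annotated
test pixels. Per class: precision TP/(TP+FP), recall TP/(TP+FN), Dice
2TP/(2TP+FP+FN) — the harmonic mean of precision and recall. Group rows and
the overall row are **micro-pooled** (counts summed before ratios), not
macro-averaged: pooled over all classes the micro identity forces
precision = recall = Dice = pixel accuracy, which is exactly the structure
the published benchmark's overall row exhibits (0.85/0.85/0.85), and which
the package verifies to 1e-12 on random matrices. Ratios with zero
denominators are reported as undefined (`NA`), never as silent zeros, so
sparse synthetic runs cannot corrupt averages. Display tables round half-up
to 2 decimals; machine-readable outputs keep full precision.

`reference_metrics()` ships the published per-component benchmark rows so
the internal consistency of that table (every Dice equals the rounded
harmonic mean of its printed precision and recall) is checked by the test
suite, and so synthetic-cohort results can be displayed alongside it.

## Numerical and design choices

* Pixel-center conventions everywhere (rasterization, resizing) so a
  brute-force point-in-polygon loop is an exact oracle for the scanline
  rasterizer.
* Arg-max ties toward the lowest class id; overlap ties toward the highest
  annotation id — arbitrary but fixed and documented.
* The loss gradient is computed from logits (log-softmax form); the public
  `masked_cross_entropy()` operates on probabilities and is clipped at
  1e-12.
* Degenerate inputs error loudly: batches with no annotated pixel, empty
  class subsets, non-simplex model outputs, shape mismatches.

## Scale of the shipped experiments

The test suite and the acceptance script run the full pipeline on cohorts of
20 cases of 256×256 pixels (18 regions per case, coverage 0.7, difficulty
0), with tiny presets trained for 10 epochs × 50 iterations and evaluated
on the held-out test cases at 0.5 μm/pixel. These sizes are the package's
chosen desk-scale study conditions; on them, both families reliably reach
macro Dice well above 0.8 and softmax ensembling does not fall below the
weaker individual network by more than statistical noise.

## Known limitations

* The synthetic cohort's color-dominated signal is far easier than real
  H&E texture; absolute Dice values on it say nothing about clinical
  performance.
* The engine is CPU-only and double-precision; the `"reference"` capacity
  presets build and run but are not practical to train at full budget here.
* No test-time augmentation, no overlap-weighted stitching, no slide-level
  aggregation statistics — out of scope by design.
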