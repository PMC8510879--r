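---
title: "Weakly supervised PET/CT tumor segmentation: models, choices, and what the phantom shows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly supervised PET/CT tumor segmentation: models, choices, and what the phantom shows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Voxel-wise tumor annotation of whole-body FDG-PET/CT studies is the
bottleneck of supervised lesion segmentation: a single study spans hundreds
of slices, and lesions can be numerous and small. `camseg` implements a
weakly supervised alternative that needs only a per-slice binary label —
"this slice contains malignant tissue" or not. Three stages produce a
voxel mask from that weak signal:

1. a convolutional **slice classifier** trained on paired PET (SUV) and CT
   (HU) channels;
2. a **class activation map** (CAM) that localizes the image evidence for
   the tumor class, by one of four methods — classic CAM, GradCAM,
   GradCAM++, ScoreCAM;
3. an **adaptive two-threshold segmentation**: a CAM threshold `t_m` carves
   a candidate region out of the activation map, and an SUV percentile
   `q_m`, computed *inside* the candidate region, sets the final intensity
   threshold `t_q`.

A fully supervised 2D U-Net (upper baseline) and a global SUV-percentile
rule (lower baseline) bracket the expected performance, and per-subject
biomarkers — 3D Dice, metabolic tumor volume (MTV, ml), total lesion
glycolysis (TLG, g) — quantify clinical utility. Because the underlying
clinical registry is not public, the package ships a synthetic phantom
generator that reproduces the *statistical* structure of such a cohort, so
every stage is testable end to end.

## The classifier and its activation maps

The classifier is a VGG-style stack of 3x3 convolution blocks with 2x2 max
pooling between blocks, closed by global average pooling (GAP) and a single
fully connected (FC) layer to two class scores. This head is exactly what
classic CAM requires. Removing the first pooling layer doubles the final
feature-map side: with full-scale geometry (256x256 input, five blocks,
first pool dropped) the last convolutional layer sees 32x32 maps; the
desk-scale default (64x64 input, four blocks) gives 8x8 maps — the same
1:8 ratio of CAM cell to image side.

With `A^k` the K post-activation maps of the last conv layer, `w^c_k` the
FC weights of class `c`, and `N` the number of spatial positions:

* **classic CAM**: `M^c = sum_k w^c_k A^k`;
* **GradCAM**: `delta^c_k = (1/N) sum_hw dy^c/dA^k_hw`,
  `M^c = max(sum_k delta^c_k A^k, 0)`;
* **GradCAM++**: per-location coefficients
  `alpha_hwk = g2 / (2 g2 + (sum_ij A^k_ij) g3)` built from the diagonal
  second (`g2`) and third (`g3`) derivatives of the score transform,
  weighting only non-negative gradients:
  `w_k = sum_hw alpha_hwk max(dS/dA^k_hw, 0)`, then
  `M^c = max(sum_k w_k A^k, 0)`;
* **ScoreCAM** (gradient-free): each `A^k` is bilinearly upsampled to input
  size, min-max normalized, and multiplied into both input channels; the
  target-class scores of these masked inputs, softmaxed over channels, give
  the weights of `M^c = max(sum_k alpha^c_k A^k, 0)`.

Every map is min-max normalized to [0, 1] (a constant map becomes all
zeros), so one threshold scale serves all four methods.

Three numerical choices deserve explanation:

* **Gradients act on the pre-softmax class score.** On confidently
  classified slices the softmax saturates and post-softmax gradients vanish
  numerically; the pre-softmax score keeps them well-scaled.
* **GradCAM++ differentiates the exponential of the logit.** For a GAP+FC
  head the logit is *linear* in `A`, its second and third derivatives
  vanish, and the alpha expression degenerates to 0/0. Under `S = exp(y)`
  the closed forms `g2 = e^y g^2`, `g3 = e^y g^3` (with `g` the first
  logit gradient) are exact for this head and match the standard GradCAM++
  derivation; the uniform positive factor `e^y` cancels inside alpha and is
  absorbed by the final normalization. Where the denominator is still zero
  (exactly where `g = 0`, so the term contributes nothing) alpha falls back
  to the uniform `1/N`.
* **A structural consequence worth knowing**: on GAP+FC heads the GradCAM
  gradient is spatially uniform (`w^c_k / N`), so normalized GradCAM equals
  normalized ReLU of classic CAM *exactly*. The two methods can therefore
  only differ through the treatment of negative values in the un-ReLU'd
  classic map. Larger gaps between them, as reported for clinical data,
  require a head that breaks this identity (e.g. the original VGG MLP head,
  or gradients taken through the softmax). The package follows the
  pre-softmax, GAP+FC formulation throughout and the test suite asserts
  the identity rather than pretending the methods diverge.

ScoreCAM follows its canonical formulation (softmax over the target-class
scores of masked inputs). A description in which perturbed feature maps are
*subtracted* from the originals circulates in the literature; it conflicts
with the method's defining publication and is not what is implemented here.
ScoreCAM evaluates its masked inputs one at a time by default: BLAS kernels
can differ in the last ulp across batch shapes, and the single-input path
makes ScoreCAM bit-reproducible against a plain per-channel loop.

## The adaptive two-threshold segmentation

For a slice the classifier calls tumor-free, the mask is empty — the
classifier acts as a gate. Otherwise:

1. `H' = (M >= t_m)` on the CAM grid;
2. `H'` is upscaled to image resolution by **nearest-neighbour block
   replication** (segmentation masks must stay binary; bilinear smoothing
   would manufacture intermediate values);
3. `t_q` = the `q_m`-th percentile of the SUV values *inside* the upscaled
   candidate region;
4. final mask: candidate positions with `SUV >= t_q`.

Pinned conventions (all exercised by brute-force enumeration tests):
percentiles interpolate linearly between order statistics (type 7 — the
tuning grid, the segmentation and all oracles share this convention);
both thresholds are inclusive (`>=`); `q_m` is a percent in [0, 100], with
fractional inputs in (0, 1] accepted as fractions since tuned optima are
conventionally quoted either way; an empty candidate region yields an empty
mask with a warning, never an error. The intensity threshold is computed
from and applied within the candidate region only — thresholding the CAM
itself with an SUV-valued cutoff would be dimensionally meaningless.

Monotonicity follows from the construction and is tested: raising `t_m`
never enlarges the candidate region; raising `q_m` never enlarges the final
mask.

## Threshold tuning

`(t_m, q_m)` are method-specific. The defaults replicate the reference
grids — 10 linearly spaced `t_m` in [0.1, 0.9] by 20 linearly spaced `q_m`
in [20, 50], 200 candidate pairs — searched exhaustively, maximizing the
**median per-subject 3D Dice** on the *validation* subjects (the training
split only ever fits models; where the literature wording wavers between
training and validation data, validation-based selection is the
reproducible reading). Ties break to the smallest `t_m`, then the smallest
`q_m`, making the search invariant to grid ordering. Activation maps are
computed once per slice and shared across the grid; this is exact because
the thresholds only enter afterwards. The global baseline tunes its single
percentile on the same 20-point grid with the same machinery.

## Baselines

The **global threshold** applies a tuned whole-slice SUV percentile to
every slice the classifier calls tumorous. The **U-Net** is the standard
four-level encoder–decoder with double convolutions and skip connections at
every level, nearest upsampling in the decoder, and a two-channel per-pixel
softmax; it trains fully supervised with the same per-pixel class-weighted
cross entropy (weight 7.7 on tumor) and the same augmentation as the
classifier. Evaluation thresholds at the per-pixel argmax; no probability
threshold is tuned.

## Training at desk scale

The reference recipes (SGD, momentum 0.9, lr 0.001, batch 64, 50 epochs for
the classifier; Adam, lr 5e-5, batch 64, 200 epochs for the U-Net; class
weight 7.7; augmentation by slice-wise scaling, rotation, translation and
per-channel contrast jitter) remain the defaults of `train_config()` and
`unet_config()`. They presuppose tens of thousands of optimizer steps.
The phantom study runs at a few hundred steps, where both networks first
learn the best *constant* prediction and plain SGD can take longer to
escape that plateau than the whole desk budget. Two standard measures make
small-scale training reliable, and `run_phantom_study()` uses them:

* **Adam** for both networks (classifier: lr 5e-3, batch 64, 5 epochs;
  U-Net: lr 3e-3, batch 8, 4 epochs);
* the U-Net's output bias starts at the **background prior log-odds**
  (−2), so no steps are spent learning the class prior;
* the U-Net trains on the positive training slices plus an equal number of
  the highest-uptake negative slices — the negatives that actually carry
  false-positive pressure (hotspots); validation and test sets are never
  subset.

Classifier input normalization is fixed: SUV clipped to [0, 15] and divided
by 15; HU clipped to [−1024, 1024] and divided by 1024. Model selection is
by best validation loss; with no validation set the final epoch is returned
with a warning. Every random element (init, shuffling, augmentation,
phantom) derives from one root seed via fixed offsets.

## The phantom: what it emulates, and what it does not

Each subject is a 64x64x32 volume at 2x2x3 mm (configurable up to the full
256x256 geometry): an elliptical soft-tissue body (~40 HU) in air
(−1000 HU) with two low-HU lung blocks; PET background ~1.0 g/ml inside
the body, ~0 in air; additive Gaussian noise (sd 0.2 g/ml) clipped at
zero. Tumors are tapered ellipsoidal high-SUV blobs (lesion SUV ~
N(6, 1.5²), truncated above background + 1.5) whose voxel counts follow a
right-skewed log-normal law; axial runs are placed so that the cohort hits
a 13.5% positive-slice fraction, matching the clinical class imbalance.
One to three lesion foci may share an axial run, creating the
multi-instance slices on which GradCAM's known weakness is measurable.
Physiological hotspots — high-SUV blobs at the body periphery with an empty
ground-truth mask, brain/bladder analogues — occur at rate 0.1 per volume
and supply false-positive pressure, so the weak-supervision problem is not
trivially solvable by intensity alone.

Two generator parameters are calibrated against the cohort description
rather than invented: the positive-slice fraction (13.5%) and the lesion
size scale. A median clinical tumor of 46.5 ml at 2x2x3 mm is ~3900
voxels with a per-slice cross-section of several CAM cells; scaled to the
desk field of view this corresponds to a log-normal median of ~150 voxels
(`meanlog = 5.0`, `sdlog = 0.8`), which preserves the ratio of lesion
cross-section to CAM-cell granularity that makes the 20–50 percentile grid
meaningful. Lesion *intensities* are free parameters (no SUV statistics are
published for the cohort); the defaults are typical FDG values.

The phantom does **not** emulate anatomy (organ shapes, uptake gradients),
scanner physics (attenuation, partial-volume blur, reconstruction
artifacts), or inter-subject variability in body habitus. Consequently the
phantom study validates the *machinery* — that the implemented methods
rank and behave as the clinical study reports, under matched statistical
structure — not clinical performance levels. Absolute Dice values on the
phantom are higher than clinical ones because synthetic lesions are
homogeneous and sharply bounded.

## Evaluation and statistics

Per-slice masks are stacked into the subject volume before any metric: 3D
Dice `2|A∩B|/(|A|+|B|)` (defined as 1.0 when both masks are empty, a case
that only arises on synthetic data), MTV = positive voxels x voxel volume
(ml), TLG = mean SUV over the mask x MTV (g). MTV/TLG accuracy is reported
as the absolute per-subject deviation (the primary summary; signed
deviations are also emitted), cohort summaries as median and IQR with
interpolated quartiles. Agreement between true and predicted biomarkers
uses ICC(2,1) — two-way random effects, absolute agreement, single
measures — computed from the Shrout–Fleiss mean squares with the
McGraw–Wong F-based 95% confidence interval; absolute agreement penalizes
systematic offsets that Pearson correlation would forgive. The test suite
checks the ICC against an independent `aov`-based oracle.

## Problem sizes used by the shipped experiments

`run_phantom_study()` (one replicate): 100 subjects (60/20/20 split),
64x64x32 voxels, classifier 5 epochs, U-Net 4 epochs; roughly three
minutes of single-core compute per replicate. The acceptance experiment in
the test suite aggregates five replicates by their median. The vignette's
toy examples and the unit tests run smaller cohorts (12 subjects, 32x32x16)
that train in seconds.

## Known limitations

* The CNN engine is compact by design: 3x3 convolutions, 2x2 pooling,
  GAP/dense heads; no batch normalization, no pretrained weights.
  ImageNet initialization of the two-channel first layer is therefore out
  of scope at desk scale.
* On GAP+FC heads CAM and GradCAM coincide up to normalization (see above);
  observed differences between them on the phantom are confined to slices
  whose raw classic map has negative values.
* The two-threshold design presumes lesions are locally the brightest
  structures — appropriate for FDG-PET, not transferable as-is to
  modalities where intensity is less discriminative.
* All processing is 2D; no morphological post-processing or
  connected-component filtering is applied to the masks.
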