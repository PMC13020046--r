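---
title: "Methods: an anchor-free fracture detector with average-pooling downsampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an anchor-free fracture detector with average-pooling downsampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Intertrochanteric femoral fractures are graded A1 (simple), A2
(multifragmentary) and A3 (transverse / reverse-oblique) under the AO/OTA
taxonomy. On radiographs the fracture is a small, low-contrast target on a
bright bone background, which makes it a stress case for single-stage object
detectors: stride-2 convolutional downsampling discards fine detail exactly
where the signal lives. `fracdet` implements a YOLOv8n-style anchor-free
detector in which downsampling sites can be replaced by *ADown* blocks, and
everything needed to study that trade: exact parameter/FLOP accounting, the
detection objective, training on CPU, evaluation, and a synthetic phantom
dataset generator standing in for clinical data that cannot be shipped.

## The detector

The baseline graph is the nano-scale member of its family: a stem
convolution (stride 2), four backbone stages of stride-2 downsample + C2f
blocks (cross-stage-partial with a channel split, stacked 3x3 bottlenecks
and a fusion 1x1), an SPPF block, an FPN top-down / PAN bottom-up neck with
two more stride-2 downsamplers, and a decoupled head that predicts, per grid
cell at strides 8/16/32, class logits and four box-edge distances encoded as
discrete distributions over `reg_max = 16` bins (decoded by the softmax
expectation, the usual distribution-focal parameterization). Scaling
constants are width 0.25, depth 0.33, max channels 1024; all convolutions
carry batch normalization and SiLU except the final 1x1 projections of the
head, which carry biases.

The ADown block replaces a single 3x3/stride-2 convolution with:

1. 2x2 average pooling, stride 1 (kernel and stride as published; padding 0
   is our choice, so a 2k x 2k map becomes (2k-1) x (2k-1) and the stride-2
   ops below, with padding 1, halve it exactly);
2. an even channel split;
3. first half: 3x3 stride-2 max pooling (padding 1) then a 1x1 fusion conv;
   second half: a 3x3 stride-2 conv (this branch-to-half order follows the
   published dataflow; the widely used reference implementation swaps the
   halves, which is parameter-identical);
4. channel concatenation back to the block's output width.

With batch-norm scale/shift counted, a plain downsample conv costs
`9*c_in*c_out + 2*c_out` learnable scalars while ADown costs
`2.5*c_in*c_out + 2*c_out` — a 72% saving per site. Whether the 1x1 fusion
conv carries normalization and activation is not specified anywhere; we
assume it does (uniform block convention); the effect is `c_out` scalars
per site.

## Accounting and the calibrated replacement set

`accounting_report()` propagates shapes through the graph and counts, per
layer, learnable parameters and multiply-accumulates (one MAC per conv
output element per kernel tap; pooling, normalization, activation and
upsampling excluded; FLOPs = 2 x MACs at 3 x 640 x 640). Under these
conventions the 3-class baseline counts 3,011,417 parameters (3.01M) and
8.1 GFLOPs, matching the published budgets.

The published description never enumerates *which* downsample sites are
replaced, only that backbone and neck sites are; the printed budgets for the
variant are 2.64M parameters and 7.3 GFLOPs. These two figures are mutually
inconsistent under the closed forms above: parameter savings are dominated
by the deep, wide sites (replacing {P4, P5, N5} alone gives 2.64M but only
7.7G, because each backbone site costs the *same* MACs — savings in FLOPs
scale with site count, savings in parameters with channel width).
`calibrate_replacement_set()` therefore enumerates all 64 subsets and
minimizes the summed relative deviation from both printed budgets. The
winner, shipped as `adown_default_sites()`, is {P2, P3, P4, P5, N5}:
2.62M parameters (0.8% below the printed 2.64M) and 7.32 -> 7.3 GFLOPs
(exact at the printed precision). The resulting reductions are 12.9% and
9.5% against the printed 12.3% and 9.8%; we document the gap rather than
force-fit it, and the full search table is returned for inspection. The stem
is never replaceable (ADown needs an even channel split of a feature map;
the stem input is the image).

## Training objective

Targets are assigned by the task-aligned scheme that is this head's
standard partner: candidate cells are those whose centers fall inside a
ground-truth box; each box takes its top-10 candidates by the alignment
metric `score^0.5 * IoU^6`; a cell claimed twice goes to the box it overlaps
most; soft class targets are the metric rescaled per box to peak at the
box's best IoU. The loss is

* classification: binary cross-entropy on all cells, per-class weighted
  (`class_weights_from_counts()` gives inverse-frequency weights normalized
  to mean 1, so minority grades A3 and A1 are penalized harder — the
  class-weighted loss enters the classification term, not the sampler);
* box: `1 - CIoU` on assigned cells, weighted by the soft target score;
* distribution focal: cross-entropy of each edge's bin distribution against
  the two integers bracketing the target distance, linearly weighted;

with component weights 7.5 / 0.5 / 1.5 (the family's defaults; the
publication names the components but not the weights) and all three terms
normalized by the summed target scores. Gradients are analytic: the BCE and
DFL terms are textbook softmax/sigmoid derivatives; the CIoU derivative is
closed-form with the trade-off coefficient treated as a constant (the
original CIoU convention), and assignment is treated as fixed within a step.
The backward pass through the network itself (im2col/GEMM convolutions,
pooling, nearest upsampling, batch norm, SiLU) is hand-written and verified
against finite differences in the test suite.

Optimization is SGD (momentum 0.937, weight decay 5e-4 on conv kernels),
cosine annealing from lr0 = 0.01 to lr0 x lrf = 1e-4 across epochs with a
3-epoch linear warmup, batch 16, 200 epochs as the nominal schedule (the
published recipe). All randomness — shuffling, augmentation, initialization
— derives from the single `train_config()` seed, which is what makes the
determinism tests exact.

## Data pipeline

Labels use the YOLO txt dialect (`class cx cy w h`, normalized); images are
grayscale, replicated to three channels (the 3-channel stem is what the
3.01M budget implies; a 1-channel stem would differ by 288 parameters).
Preprocessing is luminance conversion, aspect-preserving bilinear resize and
symmetric mid-gray letterboxing; the letterbox parameters make box mapping
exactly invertible. The splitter shuffles with a seed and takes
`floor(fraction * n)` for training — the only convention consistent with
both published counts (976 at 8:2 -> 196 test; 1,952 flip-doubled at 7:3 ->
586 validation). Augmentation is 2x2 mosaic around a jittered center with a
scale/translate affine (scale 0.5, translate 0.1), horizontal flip (p = 0.5,
`cx -> 1 - cx`), and HSV jitter — on replicated grayscale, hue and
saturation gains are no-ops by construction and only the value gain acts;
we keep the standard three-gain interface anyway. MixUp exists upstream but
is not part of the published recipe's augmentation list, so it is not
implemented.

## The phantom generator

Clinical radiographs cannot be redistributed, so `generate_dataset()`
fabricates femur-like phantoms: a bright shaft band, femoral-head disk,
neck capsule and trochanteric bulge over a darker background; a
class-specific fracture pattern carved as dark line segments (A1-like: one
oblique line at 30-60 degrees; A2-like: 2-3 intersecting lines; A3-like:
one line within 20 degrees of transverse, below the trochanter); Gaussian
blur and additive noise. The label is the tight box around carved pixels
plus a 5% margin. Class counts are apportioned by largest remainder — not
sampled — so the default mix reproduces 261/579/136 at n = 976 exactly, and
one box per image matches a table in which image and instance counts
coincide per class. Box sizes (roughly 10-30% of the image side) and
intensity levels are our choices; nothing about resolution or box statistics
is published. What passing tests on phantoms shows is that the pipeline
learns a localizable, class-separable signal end to end; it says nothing
about clinical accuracy, inter-grade ambiguity, projection geometry or
scanner variation, which is why the published clinical precision/mAP values
are used in this package only as aggregation-arithmetic checks.

## Numerical choices and problem sizes

Batch norm uses eps 1e-3 and momentum 0.03 (running stats are buffers, not
parameters). Head biases initialize to 1.0 (box) and the log-odds of a
sparse class prior (so early training does not drown in background BCE);
kernels are He-normal. NMS defaults: confidence 0.25 / IoU 0.45 for
confusion matrices, confidence 0.001 for mAP. AP uses 101-point
interpolation on the precision envelope (chosen for mAP50:95 consistency;
the published integral notation is treated as informal). Matching is
class-strict for PR/AP; only the confusion matrix records cross-class
confusion. Ties in confidence break by input order, ties in IoU by first
ground-truth index. Per-class P and R are reported at the confidence
maximizing that class's F1 — the convention of the toolchain family.
Reported reductions are computed from unrounded totals and rounded to one
decimal at the end.

The shipped tests exercise the full stack at reduced size — phantoms at
96-160 px, 64-image datasets, a training run of 220 iterations at
160 x 160 with batch 8 — which a CPU handles in minutes while still
overfitting the small set (total loss at its best iteration falls by more
than half of the first iteration's value, the designed smoke criterion; the
epoch-mean trajectory declines more gradually, by roughly 30% over the same
run). The nominal 640-input, 200-epoch schedule is available through the
same configuration objects.

## Known limitations

* Training is CPU-bound and intended for study-scale runs, not the nominal
  200-epoch clinical schedule.
* Mosaic is not automatically disabled for the final epochs of long
  schedules (upstream practice); turn `mosaic` down in `train_config()` for
  fine-tuning phases.
* The phantom generator makes no attempt at imaging physics beyond blur and
  noise; hue/saturation augmentation is inert on its grayscale output.
* The replacement-set calibration resolves an under-specified architecture
  detail; if the original authors' set differs, parameter/FLOP totals shift
  by the closed forms given above.
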