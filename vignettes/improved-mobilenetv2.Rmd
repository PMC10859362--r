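---
title: "An improved MobileNetV2 for agricultural product image classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An improved MobileNetV2 for agricultural product image classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Sorting produce by cultivar is a fine-grained image classification problem:
the Fruit-360 convention ships 100x100 photographs of single fruits on a
white background, organized as one folder per class, with many visually
similar subcategories (a dozen apple cultivars, several grape and tomato
types). MobileNetV2 is the natural backbone for the embedded devices this
task targets, but its single-scale 3x3 depthwise stage and lack of spatial
attention limit subcategory discrimination. `fruitnet` implements a
modified MobileNetV2 that addresses both points:

* **Res-Inception blocks.** Every stride-1 inverted-residual block runs its
  depthwise stage with parallel 3x3, 5x5 and 7x7 kernels. Each branch has
  its own batch normalization and ReLU6; the branches are fused by
  element-wise sum; the block keeps the usual pointwise expansion (factor
  `t`), linear pointwise projection, and the residual skip whenever stride
  is 1 and the channel counts match. Stride-2 blocks keep the original
  single-3x3 form, so the multi-kernel additions are inert exactly where
  the skip cannot exist.
* **Efficient multi-scale attention (EMA).** Between every two consecutive
  bottleneck blocks an attention module splits the channels into `g = 8`
  groups and computes, per group: a 1x1-convolution path fed by
  one-dimensional horizontal and vertical average pooling whose two
  sigmoid-gated directional descriptors multiply the group features; a 3x3
  convolution path; and two cross-spatial attention maps, each the matrix
  product of the channel-softmaxed global average descriptor of one path
  with the other path reshaped to (channels, height x width). The two maps
  are summed, passed through one sigmoid, and gate the group features
  multiplicatively, so output dimensions always equal input dimensions and
  every gate lies strictly in (0, 1).

The classifier is global average pooling over the 1280-channel head
followed by a dense softmax layer. Training uses Adam at its customary
defaults (step size 1e-3, beta1 0.9, beta2 0.999, epsilon 1e-8) with
categorical cross-entropy, batch size 32, and no schedule, weight decay,
label smoothing or early stopping; these are the published training
conditions for this architecture, and the package keeps them as defaults.

## Design decisions where the architecture was under-specified

Several details of the published architecture are not stated precisely
enough to reimplement without choices. The choices made here, and why:

* **Branch fusion is element-wise sum.** Sum is the only fusion that leaves
  the expanded width, the projection and the residual addition unchanged;
  concatenation would triple the projection and move the parameter count
  far from the documented total.
* **Per-branch batch normalization.** Each depthwise branch normalizes and
  activates before fusion, mirroring how every convolution in the original
  backbone is followed by BN + ReLU6.
* **EMA insertion granularity.** "Between every two modules" is read at the
  finest granularity that the documented parameter total supports: one EMA
  module at each of the 16 interior boundaries between consecutive
  bottleneck blocks.
* **EMA convolutions are grouped convolutions with biases and no
  normalization layer.** The channel groups are realized as a grouped
  convolution over the full width, i.e. each group has its own 1x1 and 3x3
  weights (the TF/Keras-natural construction, with the framework-default
  biases). Weight sharing across groups (folding groups into the batch
  axis) was evaluated and rejected during calibration: it shrinks the
  attention module to a few thousand parameters and leaves the build about
  5% below the documented total, while the grouped-convolution reading
  lands within 0.02% of it.
* **Descriptor normalization.** The globally pooled descriptor is
  channel-softmaxed before the matrix product, so each attention map is a
  convex combination of the other branch's channel responses and its scale
  does not grow with the group width.
* **Aggregation of the two maps** is element-wise sum followed by a single
  sigmoid — the reading in which one aggregation feeds one squashing.
* **Parameter-count calibration.** With these choices the default
  131-class, 100x100-input build counts 3,028,675 trainable parameters
  against a documented reference of 3,028,211 (+464, +0.015%). An
  exhaustive search over the admissible readings (branch sets, fusion
  rules, shared vs per-branch normalization, every natural insertion-site
  set, shared vs grouped vs full-width attention convolutions, bias and
  group-norm variants, trainable-only vs total counting) produced no
  configuration matching the reference exactly; exact matches exist only
  for arbitrary subsets of insertion sites, which would be numerology
  rather than a design. The package therefore ships the nearest principled
  configuration and reports its count as computed; `model_param_breakdown()`
  and the CLI's `build-info --report-params` print the per-component audit
  that makes the residual gap inspectable.
* **Ablation toggles.** `use_res_inception` and `use_ema` are first-class
  switches of `default_architecture()`; disabling both reproduces the plain
  width-1.0 MobileNetV2 backbone (2,391,683 parameters with a 131-class
  head), which the test suite asserts.

## Numerical choices

* Batch normalization uses biased batch variance, epsilon 1e-3 and running
  statistics with momentum 0.9; convolutions carry no bias wherever BN
  follows (the EMA convolutions, which have no normalization, do carry
  biases). After training, the running statistics are recalibrated as the
  exact sample-weighted average of batch statistics over the training set
  (precise-BN); on small datasets the exponentially decayed estimates
  otherwise lag the per-batch statistics the network was fitted under,
  costing a few points of inference-mode accuracy.
* Initialization is He-normal for convolutions, gamma = 1 / beta = 0 for
  BN, Glorot-uniform for the classifier; all draws happen under the single
  seed passed to `build_model()`, so identical seeds give bit-identical
  parameters and outputs.
* Forward/backward computation is double precision throughout; all
  oracle-comparison tests use tolerances of 1e-6 relative or tighter.
  Argmax prediction breaks ties by the first (lowest-index) class.
* "Same" spatial padding follows the convention in which the extra pixel of
  an odd total pad goes to the bottom/right, and output sizes are
  `ceiling(input / stride)`; a 100x100 input therefore reaches the head as
  a 4x4 map. Builds reject inputs whose stride schedule would downsample a
  one-pixel map, naming the offending block.
* Image preprocessing resizes with separable bilinear interpolation under
  the half-pixel-center convention and maps pixels linearly from [0, 1] to
  [-1, 1]. The resize is implemented as two small weight-matrix products,
  which pins the boundary behaviour to the documented mapping and makes it
  directly checkable against a loop oracle.
* The backward pass of every layer (including the full attention module) is
  hand-derived and verified against central-difference directional
  derivatives in the test suite.

## The synthetic fixture generator

`generate_fixture()` emulates the layout and photographic conventions of
the real data — one folder per class, a single centered object on a white
background, 100x100 pixels — with each class a distinct (shape, hue)
family: shapes cycle through disc, square, triangle, ring, cross and
diamond, hues are evenly spaced on the color wheel, and each image jitters
size (±15%), rotation, position (±8% of the field), hue (±0.02) and value,
plus additive Gaussian pixel noise (sd 0.02 in [0, 1] units, the default).
Images are quantized to 8 bits at generation, so the in-memory set and an
on-disk PNG round-trip are bit-identical, and generation under a fixed seed
is byte-reproducible.

The standard study fixture used by the acceptance tests is 5 classes x 40
images at size 100 — large enough that a 3M-parameter network must actually
learn color/shape features to overfit it, small enough to train on one CPU
in minutes. What passing these tests shows is that the architecture,
gradients and training loop are correct and that the model can fit a
separable class structure; it does not show real-data accuracy, because the
fixtures lack the photographic variability (pose, texture, specularity,
near-duplicate cultivars) that makes Fruit-360 hard. The published
headline accuracies require the real dataset and GPU-scale training and are
deliberately out of scope here.

## Problem sizes in the test and acceptance runs

Module tests run on tensors of a few thousand elements plus numeric
gradient checks. The acceptance suite trains the full model once on the
5x40 fixture at size 100 with batch 32, stopping once training accuracy
reaches 97% (slightly past the 95% bar it asserts, so the recalibrated
running statistics settle; always within the 30-epoch bound); evaluates a
frozen-random model on a balanced 5x20 fixture to confirm chance-level
accuracy; and runs all four ablation configurations for one epoch on a
3x8 fixture at size 64. These sizes were chosen as the smallest runs that
still exercise every component end to end.

## Known limitations

* Only dense/depthwise/grouped square-kernel "same"-padded convolutions are
  implemented — exactly what the architecture needs, nothing more.
* Training is single-threaded CPU (BLAS-backed matrix products); it is
  meant for fixtures and small datasets, not for the full 90k-image corpus.
* Batch-norm statistics with very small batches (one or two images) are
  noisy; the defaults (batch 32) avoid that regime.
* JPEG decoding requires EBImage; PNG is handled natively and is the format
  the generator writes.
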