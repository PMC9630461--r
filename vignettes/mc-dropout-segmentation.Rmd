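---
title: "Monte Carlo dropout UNet segmentation: model, assumptions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte Carlo dropout UNet segmentation: model, assumptions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Automatic segmentation of lesions in clinical photographs (the
motivating application is screening for potentially malignant oral
lesions) is well served by UNet-style encoder–decoders, but a plain
network reports only a softmax map, which is routinely — and wrongly —
read as confidence. For clinical use the model should also say *where
it does not know*: lesion borders are genuinely ambiguous even for
specialists, and a prediction that is wrong without warning is worse
than one flagged for review. This package implements the Bayesian
answer: Monte Carlo (MC) dropout, which turns a single trained network
into an approximate posterior over networks and reads uncertainty off
the spread of its predictions.

## Model and estimators

A Bayesian network places a distribution over its weights `W` and
predicts through the posterior predictive integral. Dropout variational
inference approximates this by keeping Bernoulli dropout active at test
time: each stochastic forward pass realizes one weight draw `Wᵢ`.
With σ passes,

* posterior mean: `p(y*|x*,X,Y) ≈ (1/σ) Σ Softmax(f^{Wᵢ}(x*))`,
* uncertainty: the per-class *population* variance
  `v = (1/σ) Σ (p(y|x*,Wᵢ) − p(y|x*,X,Y))²`.

Estimator choices made here, where the printed formulas leave room:

* **Population (1/σ), not sample (1/(σ−1)) variance** — following the
  formula as printed.
* **Class reduction.** The formula is per class but uncertainty maps are
  single-channel; we average the per-class variances over classes. For
  binary softmax the two class variances are identical, so the
  reduction is lossless in the intended setting.
* **Normalization scope.** Pixel uncertainties are min–max normalized
  to [0,1] *per image* (matching per-image heatmap rendering); the
  functions accept any pooled map, so per-dataset normalization is a
  caller-side choice. A constant variance map normalizes to all zeros
  rather than NaN: a map with no contrast carries no uncertainty signal.
* **Ties.** Argmax label ties break toward the lower class index, for
  determinism.

The label mask is the argmax of the posterior mean. With dropout
disabled the sampler is deterministic, the variance is exactly zero, and
every "uncertainty" downstream is zero by the constant-map convention —
this degenerate chain is asserted in the tests.

## Architecture

`depth` contracting blocks (two 3×3 convolutions + ReLU, then 2×2/stride-2
max pooling, channels doubling), a two-convolution bottleneck, mirrored
expansive blocks (2×2 up-convolution halving channels, skip
concatenation, two 3×3 convolutions + ReLU), and a 1×1 softmax head.
Dropout (default rate 0.5) is placed after each max pooling and/or
immediately after each up-convolution — *before* the skip concatenation,
which is the literal reading of "following the up-convolutional layer";
placing it after concatenation would also perturb the skip path, which
the description does not state.

Further choices where the source description is silent:

* **Same padding, no cropping.** The classic UNet crops skip features
  because of valid-padding shrinkage; with same padding the output is
  full-size, matching full-image masks, and "correspondingly cropped"
  becomes the identity.
* **Configurable width.** The published model's channel widths are not
  printed (its stated size implies a reduced UNet, not the original
  64→1024 design), so `depth` and `base_channels` are free parameters;
  desk-scale defaults are depth 4 / base 16 for the config object and
  depth 2 / base 8 in the experiment driver.
* **Separable variant.** Every 3×3 convolution in both paths becomes
  depthwise (3×3, per channel) + pointwise (1×1) with one bias; the 2×2
  up-convolutions and 1×1 head stay conventional — 1×1 and 2×2 kernels
  gain essentially nothing from factorization, and the description says
  the *convolutional layers* were replaced.
* **Loss and extras.** Pixel-wise unweighted cross-entropy (no loss is
  named in the source; class weighting is never mentioned), no batch
  normalization (never mentioned), plain Bernoulli dropout rather than
  spatial dropout ("MC dropout" plainly).
* **Initialization.** He-normal, bias zero.

There is no deep-learning framework dependency: convolution
forward/backward is im2col + GEMM in RcppArmadillo, with max pooling,
2×2 stride-2 transposed convolution and depthwise convolution as small
C++ kernels and Adam in R. Correctness is established by
finite-difference gradient checks over every parameter tensor and by
plain-R convolution oracles; this is why the package can honestly claim
its MC samples mean what the formulas say.

## Training protocol

Adam (default learning rate 1e-3 — the protocol states Adam and batch
16 but no rate), minibatch size 16 by default, validation-loss
checkpointing with the strict-decrease rule: the kept model is the one
after the epoch with the lowest validation loss seen so far. Validation
loss is computed with dropout *off*: checkpoint selection should not be
a lottery over dropout masks. Training-mode loss keeps dropout on, as
usual.

Augmentation draws, per copy, a random composition of horizontal and
vertical flips (p = 0.5 each), rotation ±25°, zoom 0.85–1.15,
brightness ×0.8–1.2 and gamma 0.7–1.4; the geometric part is applied
identically to image and mask (mask by nearest neighbour, re-binarized),
the photometric part to the image only, intensities clipped back to
[0,1]. The operation list is as published; the ranges are not, and were
chosen once as modest, label-preserving perturbations.

Cross-validation splits the data into k seeded folds. Augmentation
happens *inside* each fold, on the training portion only — the
leakage-free reading, since the source does not say whether augmentation
preceded the split. Because a checkpoint-selection set must be disjoint
from the test fold, 10% of each fold's training portion (seeded, at
least one sample) is held out as validation; this split is an artifact
of our implementation, not of the source protocol. Per-fold metrics
pool pixel counts over the fold's test images (micro-average); the
aggregate reports mean and sd across folds. Whether the published
tables micro-average or average per image is unstated; both are
available (call the metric functions on single images for the latter).

## Evaluation semantics

* **Pixel accuracy** is global: correct pixels over all (valid) pixels.
* **Per-class IoU** `TP/(TP+FP+FN)`; **mean IoU** averages classes
  *present in the ground truth* (a class absent from the ground truth
  within the valid area is skipped, not scored 0 or 1 — otherwise every
  negative image would pin mean IoU regardless of the prediction);
  **weighted IoU** weights by ground-truth pixel share.
* **Dice** `2TP/(2TP+FP+FN)` is reported for the lesion class, the
  clinically relevant foreground; a per-class table is also emitted.
* **Patch metrics** use non-overlapping 2×2 windows, accuracy threshold
  0.5 *strict* (a patch with exactly half its pixels correct is
  inaccurate, per the stated "higher than 0.5"), and uncertainty
  threshold strict on the complement (boundary values count as certain).
  One sentence in the source says the *PAvPU value* is compared with the
  uncertainty threshold; that is internally inconsistent with the metric
  definitions and is read as the average patch uncertainty — the only
  interpretation under which the three formulas are computable.
* **Undefined quotients** (e.g. no inaccurate patches) return a
  documented `NA` sentinel, never an error: limit thresholds
  legitimately empty categories.
* **Removal analysis**: for threshold t, pixels with uncertainty > t
  are removed and metrics recomputed on the rest; t = 1 reproduces the
  unmasked report exactly, and the remaining-pixel ratio is
  non-decreasing in t. The threshold for a target remaining ratio is the
  type-1 quantile of the pooled uncertainties (target 1 → 1.0).
* Images whose sides are not multiples of the patch size have their
  trailing remainder truncated, with a warning.

## The synthetic data generator

The clinical dataset behind the reference results (492 white-light
photographs, 396 positive / 96 negative) is private. The generator
emulates the *statistical structure the method needs*, not oral
anatomy: a skin-toned background with low-frequency texture and
per-sample tone jitter; in positive samples (80% by default, matching
the screening-style class balance) one to three irregular blobs —
radially modulated Gaussian bumps — whose colour shifts smoothly toward
red; per-pixel Gaussian noise (sd 0.04). The ground-truth mask
thresholds the *pre-blur* bump field at half its peak, so the label
boundary is exact and reproducible, while the rendered image uses the
field blurred at `border_softness` (2.5 px), making the visible border
diffuse. Border uncertainty in a trained model is therefore *emergent*:
nothing marks the border in the input except genuine ambiguity.

Deliberate simplifications, hence what a green test does **not**
establish: one lesion appearance (no leukoplakia-vs-erythroplakia
colour split), no specular highlights, teeth, motion blur or anatomy,
no annotation noise, and a colour cue that is more learnable than real
lesions. Passing the end-to-end criteria shows the pipeline is wired
correctly and reproduces the *directions* of the published effects
(uncertain pixels are less accurate; uncertainty concentrates at
borders); it says nothing about clinical performance, and the published
table values are quoted nowhere as expectations.

Image size defaults to 128 px (64 px in desk-scale runs); the source
never states its resolution. Positive/negative allocation is
deterministic (`round(fraction × n)`) rather than Bernoulli, for
testability. Identical parameters and seed give bit-identical datasets,
and the generator restores the caller's RNG state.

## Numerical and degenerate-input conventions

* Softmax is computed with per-pixel max subtraction; cross-entropy
  clamps probabilities at 1e-12.
* Input sides must be divisible by 2^depth; violations raise an error
  naming the required divisibility (no silent padding).
* `sigma = 1` yields a mean equal to the single sample and zero
  variance; sampling a dropout-free model warns and yields identical
  samples.
* Constant uncertainty maps normalize to zero (see above); empty
  denominators in patch metrics yield `NA`.
* A threshold that removes every pixel produces an `NA` metric row and
  the curve continues.

## Scale choices in the tests

The published protocol (300 epochs, 10-fold CV, σ = 100, 6×
augmentation, batch 16) is desk-hostile on one CPU; all of it is
reachable through `train_config()`/the YAML config, and the end-to-end
acceptance experiment runs a scaled-down but structurally identical
protocol: 200 synthetic 64×64 images, 2-fold CV, depth-2/base-8 model,
15 epochs, batch 8, 2× augmentation, σ = 25 — chosen once for
single-CPU trainability (≈6 min) and not tuned against the acceptance
thresholds; the first full-scale run cleared every criterion with wide
margins (held-out mean IoU ≈ 0.83 against the 0.70 bar).

## Known limitations

* Single-image minibatch accumulation (no batched GEMM across images);
  training speed is adequate for desk scale only.
* Epistemic uncertainty only — the variance of MC samples; no
  aleatoric head, predictive entropy or mutual information.
* Binary masks are the tested path; `n_classes > 2` is supported in the
  network and metrics but the generator only emits binary problems.
* The checkpoint stores the full parameter list as RDS; portability of
  checkpoints across package versions is not guaranteed.
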