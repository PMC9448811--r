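---
title: "Grading gland textures with multi-channel fused attention: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading gland textures with multi-channel fused attention: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its science: the model and
its assumptions, the parameters that matter, what the synthetic data can
and cannot stand in for, and the numerical and design choices that were
genuinely open.

## The grading task

Colorectal adenocarcinoma is graded by glandular differentiation: the
fraction of tumor area still organized into gland structures. Grade I
(highly differentiated) shows more than 95 % glandular area, grade II
(moderately) 50–95 %, grade III (poorly) 5–50 %. The classifier sees an
RGB patch and returns one of the three grades. Clinical H&E patches of
this kind are typically private; everything here is therefore exercised on
synthetic gland textures whose ground truth is known exactly.

## The attention block

Given a backbone feature map $FM \in \mathbb{R}^{H\times W\times C}$, one
selective-kernel (SK) channel-attention branch computes two
channel-preserving convolutions $U_3 = f^{3\times3}(FM)$ and
$U_5 = f^{5\times5}(FM)$, pools their sum globally, and squeezes it
through a bottleneck $C \to \lceil C/r\rceil \to C$ with a rectifier
between and a sigmoid at the end, producing a per-channel gate $M_a$ with
complement $M_b = 1 - M_a$. The branch output is
$FM_c = M_a \otimes U_3 \oplus M_b \otimes U_5$: each channel mixes the
3×3 and 5×5 receptive fields with complementary weights, so a channel's
effective receptive field adapts to its input.

Two readings of the block's defining equations were genuinely open, and
the package fixes them as follows:

* **Gates must act on the branch outputs, not the input.** Read literally,
  $FM_c = (M_a \otimes FM) \oplus (M_b \otimes FM) = FM$ — an identity,
  because the gates are complementary. The block implements the SK
  semantics above instead, which is the construction the mechanism is
  named after; anything else would make the branch a no-op.
* **Output channel count is 3C.** The fused block concatenates the three
  branch outputs at reduction ratios 4, 8, 16 into an $H\times W\times 3C$
  map. The printed fusion multiplies this with the $C$-channel input and
  still states a $3C$-channel result; the only shape-consistent reading
  replicates the input three times along channels for that product, and
  applies the spatial attention to the product (not the original map).
  The package follows that reading and does not silently switch.

Spatial attention pools the fused product channel-wise (average and
maximum), concatenates the two $H\times W$ maps, convolves them with a
7×7 kernel and applies a sigmoid, giving
$FM_s \in (0,1)^{H\times W\times 1}$ which re-weights every channel of the
product. All attention convolutions use stride 1 and zero-padded "same"
borders — required so the elementwise products are shape-consistent.

Structural invariants follow directly and are asserted in the tests:
$M_a + M_b = 1$ exactly; gates and spatial maps lie strictly inside
$(0,1)$; one SK branch preserves shape; the fused block triples the
channel count.

## Network, fusion and head

The backbone is the VGG16 convolutional stack: thirteen 3×3 convolutions
in five blocks, 2×2 max pooling after each block, so a $224\times224\times3$
input yields a $7\times7\times512$ map. A `width_multiplier` scales every
stage's channel count for CPU-scale work; the fusion relation is
unaffected. Fine-tuning freezes everything before a named layer, by
default the first convolution of block 3 — the boundary name
(`Block_Conv3`) is ambiguous between "third block" and "third convolution
of a block"; the package freezes up to the third *block* and accepts the
original spelling as an alias. The boundary is configurable, so the other reading costs one
argument.

The attention branch hangs off the backbone's final convolutional map in
parallel with an identity path, and the two are fused by channel
concatenation ($C + 3C = 4C$). The fusion operator was described only as
"fused"; concatenation was chosen because it preserves both signals and
lets the head learn their weighting. The head is the smallest standard
one: global average pooling, one affine layer to 3 logits, softmax.
Pretrained backbone weights can be supplied through an option
(`hccanet.vgg16_weights`) but are never required; default initialization
is uniform with fan-in scaling at the rectifier-preserving (He) bound
$\pm\sqrt{6/\text{fan-in}}$, seeded and reproducible — with the classical
$\sqrt{1/\text{fan-in}}$ bound the signal measurably dies across the
thirteen rectified layers.

## Image preparation

Four denoising families are provided — mean, median, gaussian, bilateral —
applied per channel with replicate borders, at odd window sizes (the
reference protocol sweeps 3, 5, 7 and settles on gaussian/5). The gaussian
sigma is not part of the protocol; it derives from the window as
$\sigma = 0.3\,((k-1)/2 - 1) + 0.8$, the common kernel-to-sigma
convention, and is configurable. Bilateral sigmas default to 75/75
(intensity units / pixels), the widely used defaults. Resizing is
bilinear with half-pixel centre alignment. Standardization treats every
pixel–channel position as a feature: subtract the training-set mean,
divide by the training-set standard deviation (the protocol's wording
"divides by its variance" describes the standard scale transform, whose
unit-variance claim only holds when dividing by the standard deviation),
with zero-variance features mapped to 0. The order is denoise → resize →
standardize, and the standardizer is fitted on the training split only —
fitting on everything would leak test statistics through the
normalization.

## Synthetic data: what it emulates and what it does not

`generate_image()` renders ring-shaped "glands" — bright lumen, dark
epithelial rim — over a smoothed pink stroma texture, then adds gaussian
pixel noise (default sd 8 on the 0–255 scale, enough to make denoising
non-trivial without burying the structure). The target gland coverage is
drawn uniformly from the grade's interval; disks are placed greedily,
shrinking any proposal that would overshoot the interval's upper bound, so
the realized coverage of the ground-truth mask always lies inside the
requested interval. Images come in groups of six sharing a source
identifier, mirroring several patches cut from one tissue section. The
default dataset is 210 images per grade (630 total) at 448×448, scalable;
tests and the acceptance script run at 48–64 px, where a full generation
plus augmentation cycle takes seconds.

What passing tests show: the pipeline's bookkeeping (splits, balance,
traceability) is exact; the architecture can learn a coverage-driven
texture signal from scratch; heatmaps of a trained model align with the
planted signal. What they do not show: performance on real H&E stains —
the generator does not emulate stain variability, nuclear morphology,
imaging artifacts, or inter-patient heterogeneity, so no accuracy measured
here transfers to clinical data.

## Splitting, augmentation, cross-validation

The split is stratified 8:1:1 with floor allocation and remainders going
to the training subset (deterministic, and the conventional
larger-split choice): 630 images give 504/63/63, i.e. 168/21/21 per
class. The reference protocol splits at image level even though six
patches share a section; a `group_key` argument optionally keeps whole
sources in one subset (subset sizes then only approximate the ratios and a
warning reports the shortfall). The default mirrors the image-level
protocol, with the leakage caveat documented here.

Augmentation grows the training split to a fixed total (default 4500,
1500 per class — balance is enforced because the input classes are
balanced) by rotation within ±30°, random crops at side fraction 0.8–1.0
resized back, and zooms at 0.9–1.1. The reference protocol names exactly
these three operations (with an open-ended "etc."); the package closes
the set to them, with conventional, configurable ranges. Every variant logs its source item and parameters,
and the log is reproducible from the seed.

Both evaluation modes of the reference protocol exist: the fixed 8:1:1
split (the headline pipeline) and stratified five-fold cross-validation
(`kfold_cv()`, which refits the standardizer inside each fold). The
protocol uses both without reconciling them, so the package makes both
available rather than guessing which produced which table.

## Training and its desk-scale parameters

Training is minibatch Adam (β₁ = 0.9, β₂ = 0.99, ε = 1e-8) under
categorical cross-entropy, with per-epoch train/validation history and
retention of the best-validation parameter snapshot. No early stopping —
the reference protocol never mentions it — only checkpointing. Divergence
to a non-finite loss aborts with an error rather than returning garbage.

`train_config()` defaults to the reference protocol: learning rate 0.005,
100 epochs, batch 32. The package's own sanity runs — 60 training images
at 64×64, width multiplier 1/8, seeded random initialization — use
learning rate 2e-4, batch 8, 15 epochs instead: the reference rate
assumes an ImageNet-pretrained backbone being fine-tuned on thousands of
augmented images, and at desk scale from random initialization Adam at
0.005 oscillates without converging. This is a deliberate package choice
for the small-scale regime, not a revision of the protocol defaults.
Under it the width-shrunk network reaches 93–100 % training accuracy
within 10 epochs (and 100 % by 15) and 75–92 % accuracy on 90 fresh
synthetic images (chance 33 %), with macro one-vs-rest AUC around
0.91–0.98 across the seeds tried — numbers the acceptance script
recomputes on every run.

## Metrics

`compute_metrics()` builds the 3×3 confusion matrix and per-class
precision $TP/(TP+FP)$, recall $TP/(TP+FN)$, $F_1 = 2PR/(P+R)$ and overall
accuracy. Zero-denominator rates return 0 and are flagged rather than silently
dropped. `roc_auc_ovr()` computes one-vs-rest AUC by the rank
(Mann–Whitney) statistic with midrank ties — exactly the probability a
positive outranks a negative — and reports the unweighted macro average
(classes are balanced, so weighting is moot); a class absent from the
truth vector yields `NA` with a flag. Both are verified in the tests
against brute-force oracles: an explicit counting tally and the
exhaustive pairwise comparison.

## Grad-CAM

The heatmap at a layer is the rectified, gradient-weighted sum of its
activations: channel weights are spatial means of the gradient of the
**pre-softmax** class logit (softmax gradients saturate; the pre-softmax
score also makes the map invariant to a constant shift of all logits,
which the tests assert), bilinearly upsampled to the input size and
min-max normalized per image to [0, 1]. An identically zero rectified map
stays zero and is flagged instead of being divided by zero; a constant
positive map normalizes to all ones. The default target layer is the
fused map the classifier head consumes — the quantity the model actually
decides on; any backbone convolution can be named instead. Overlays blend
a blue (unimportant) to red (critical) diverging colormap whose red
channel is monotone in the heatmap value, so the reddest pixel is the
heatmap peak.

## Numerical choices and degenerate inputs

* Convolutions in the network engine use zero-padded "same" borders;
  image-space filters use replicate borders (an image's edge is not
  zero-valued tissue).
* The SK bottleneck width is $\lceil C/r \rceil$, so ratios larger than
  the channel count degrade gracefully to a width-1 bottleneck instead of
  an empty layer.
* Max pooling uses floor semantics; backbone input sizes must be
  divisible by 32 so five poolings are exact.
* Ties in channel-wise max pooling (spatial attention) route the gradient
  to the first maximal channel; ROC ties use midranks.
* The cross-entropy clamps probabilities at 1e-12 before the log;
  softmax subtracts the max logit before exponentiating.
* Zero-variance features standardize to 0; an all-zero Grad-CAM map is
  flagged, not renormalized.

## Problem sizes

The test suite and acceptance script run, as a package choice, at:
synthetic images of 48 px (pipeline counts: 630 images, 8:1:1 split,
augmentation to 4500) and 64 px (learning runs); width multiplier 1/8
(learning) and 1 (single structural forward passes at 224 px and the
2048-channel fusion check); 100 seeded 4×4×2 feature maps for the
equation-oracle comparisons at tolerance 1e-5. The full suite completes
in a few minutes on one CPU.

## Known limitations

* No stain normalization or color deconvolution; the generator's colors
  are stylized, not calibrated H&E.
* The engine is single-threaded CPU code; it is meant for correctness and
  desk-scale experiments, not for training at 224 px and width 1.
* Pretrained ImageNet weights are an optional hook; nothing in the
  package reproduces pretraining.
* Image-level splitting (the default, mirroring the reference protocol)
  lets patches from one section appear in different subsets; use
  `group_key = "source"` when that leakage matters.
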