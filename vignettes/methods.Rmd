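---
title: "Two-view semi-supervised attention networks for 3D cardiac segmentation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-view semi-supervised attention networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Voxel-accurate segmentation of cardiac structures (an atrial or ventricular
cavity in MRI or 3D ultrasound) is limited by annotation cost: expert labels
exist for a handful of scans while many more go unlabeled. tpssan implements
a semi-supervised training scheme that learns from a small labeled pool plus
a large unlabeled pool, built from four cooperating parts:

1. **Mean-teacher training.** Two copies of one segmentation network are
   kept: a *student* updated by SGD and a *teacher* updated as an
   exponential moving average (EMA) of the student,
   $\theta_t \leftarrow d\,\theta_t + (1-d)\,\theta_s$. The teacher sees
   noised unlabeled inputs and supplies hard pseudo-labels; prediction at
   test time uses the teacher (a student flag exists).
2. **Two-view slice-confidence supervision.** The middle transverse slice
   and the middle coronal slice act as "source slices". Every slice at
   index distance $d$ from the source receives confidence $w^d$ for a decay
   factor $w \in (0, 1]$ (1 at the source, exponential decay elsewhere).
   The two per-view maps are fused voxelwise — by product by default — into
   a weight map $W$ that multiplies both the supervised and the
   pseudo-label losses.
3. **Volumetric CutMix.** Pairs of unlabeled patches are mixed by cutting a
   box from one into the other, $\tilde{x} = M \cdot x_A + (1-M) \cdot x_B$
   with a binary box mask $M$; the teacher's pseudo-labels are mixed with
   the *same* mask. The mixing ratio $\lambda$ is drawn from
   Beta$(\alpha,\alpha)$ with $\alpha = 1$ (uniform on $(0,1)$).
4. **Uncertainty-rectified multi-scale consistency.** The network emits a
   pyramid of $S$ class-probability maps $p_0 \dots p_{S-1}$ (all upsampled
   to full resolution) with average $p_c$. Per scale and voxel, the KL
   divergence $D_s = \sum_j p_s^j \log(p_s^j / p_c^j)$ measures how far a
   scale strays from the consensus; the consistency penalty
   $(p_s - p_c)^2$ is weighted by $e^{-D_s}$ (rectification) and the
   magnitude $\lVert D_s \rVert^2$ is itself penalized (uncertainty
   minimization).

The total loss is
$L = L_{sup} + L_{semi} + \lambda(t)\, L_{unsup}$,
where $L_{sup}$ and $L_{semi}$ are each the equal-weight combination of a
weighted cross-entropy
$-\sum_i w_i \log p_i[y_i] / \sum_i w_i$
and a weighted Dice loss
$1 - 2\sum_i w_i y_i p_i / \sum_i w_i (p_i^2 + y_i^2)$,
with $y$ the ground-truth label for $L_{sup}$ and the teacher pseudo-label
for $L_{semi}$.

## The network

The segmentation backbone is a VNet-style residual encoder-decoder
(strided-convolution downsampling, transposed-convolution upsampling, skip
concatenations, channel widths doubling per level from `base_channels`).
Two attention mechanisms can be placed in it:

* **CBAM** on a configurable subset of the down/up stages: channel
  attention (a shared bottleneck MLP over the global average- and
  max-pooled channel descriptors, summed, sigmoid-gated) followed by
  spatial attention (a sigmoid-gated convolution over the channel-wise
  average and max maps).
* An **adaptive channel attention block** after the input stem: a
  parameter-free gate `sigmoid(global average pool)` multiplied into the
  features.

`make_variant(1..5)` reproduces the five studied placements: (1) CBAM on
all four downsampling stages; (2) input attention + CBAM on three
downsampling stages; (3) input attention + CBAM on all four downsampling
stages — the proposed configuration; (4) input attention + CBAM on the four
upsampling stages; (5) the plain VNet.

Because no deep-learning framework is part of this package's dependency
footprint, the network runs on a compact reverse-mode autodiff engine
(`R/autograd.R`): a tape of recorded operations over plain R arrays, with
the convolution, transposed-convolution and trilinear-upsampling kernels in
C++ (im2col + BLAS GEMM). Every loss used in training is checked against
independently written scalar-loop oracles, and gradients are verified by
central finite differences in the test suite.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `decay_weight` | 0.95 | per-slice confidence decay; 1 disables weighting. The functional form $w^d$ is fixed; the base is configurable per run because no canonical value exists. |
| `combine_rule` | product | fusion of the two view maps; product demands both views be confident, `max`/`mean` are available. |
| `augment.cutmix.alpha` | 1 | Beta concentration of the mixing ratio (uniform draw). |
| `augment.cutmix.prob` | 0.5 | probability a batch's unlabeled patch is replaced by a CutMix of two unlabeled patches. |
| `lambda_unsup` | 0.1 | peak consistency weight; ramped in with a Gaussian schedule $e^{-5(1-t/T)^2}$ over `rampup_length` iterations, defined as exactly 0 at $t=0$. |
| `ema_decay` | 0.99 | teacher EMA; the phantom demo overrides it to 0.95 because a ~100-step schedule cannot wait for a 0.99 teacher to catch up. |
| SGD | lr 0.01, momentum 0.9, weight decay 1e-4 | momentum and weight decay are the values standard in this literature; the base learning rate and its polynomial decay (exponent 0.9) are this package's choices. The demo uses lr 0.02 for its short schedule. |
| `pyramid_scales` | 4 | heads on the decoder outputs at full, 1/2, 1/4 and 1/8 resolution, each a 1-voxel classifier plus trilinear upsampling. |
| `reduction_ratio` | 16 | CBAM MLP bottleneck, clamped per stage to [2, C] and required to divide C. |
| `spatial_kernel` | 7 | CBAM spatial convolution; zero padding keeps any feature size valid, so no clamping is needed on small grids. |

## The phantom generator

`generate_phantom()` emulates a single-foreground-structure cardiac volume:
one bright, randomly oriented ellipsoidal chamber with tubular appendages
rooted on its surface (an atrial body with vessel stumps), a smooth
low-order polynomial multiplicative bias field (qualitative stand-in for
MRI coil inhomogeneity), and additive Gaussian noise. The label is the
exact chamber-plus-tubes mask. Generation is bit-deterministic in
(spec, seed), the foreground is a single 26-connected component, and with
noise far below the class-mean gap a global threshold recovers the label at
Dice ≥ 99 — so the task is learnable by construction.

What the phantom deliberately does **not** model: multi-structure anatomy,
ultrasound speckle physics, cardiac/respiratory motion, scanner-specific
artifacts, and inter-rater label noise. Passing the phantom benchmark
therefore demonstrates that the training machinery works and that the
semi-supervised signal helps on this family of images; it does not certify
clinical performance.

## Numerical choices

* Probabilities inside logarithms and KL terms are floored at
  $\varepsilon = 10^{-7}$; gradients are zeroed where the floor binds.
* The consistency loss normalizes the rectified term per scale by
  $\sum_v w_s^v$ (invariant to uniform rescaling of the weights) and the
  uncertainty-minimization term by the voxel count, so the loss is
  resolution-independent; the per-scale terms are then averaged over $S$.
  The rectification weight $w_s^v = e^{-D_s^v}$ follows the uncertainty-
  rectification design this loss family is based on.
* Weighted Dice on an empty-foreground/zero-prediction pair is defined as 0
  with a warning; an all-zero weight map is an error.
* CutMix box sides are $\text{shape} \cdot (1-\lambda)^{1/3}$ rounded per
  axis (volume-fraction generalization of the 2D area convention); the box
  lies fully inside the grid and the recorded ratio is the realized mask
  fraction, not the drawn $\lambda$.
* Sliding-window offsets shift the last patch inward so the patch shape is
  always honored (no padding); overlaps fuse by arithmetic mean; the
  default stride is half the patch (no published value exists).
* Axis convention: R arrays indexed (x, y, z), 1-based, z the transverse
  stacking axis. Slice distances are measured in slice indices, not
  millimetres.
* Instance normalization (batch-independent) keeps batch size 2 stable; a
  one-voxel bottleneck (e.g. a 16³ patch through four levels) degenerates
  under it, so practical patches keep at least 2 voxels per axis at the
  deepest level.
* 95HD uses linear interpolation between order statistics and pools the
  two directed surface-distance sets before taking the percentile; surfaces
  are face-connected border voxels (out-of-grid counts as background).

## Design decisions that were genuinely open

* *What the pyramid heads attach to and S*: the four decoder stages
  (plus optionally the bottleneck for $S = L+1$); $S = 4$ by default.
* *"Element-wise convolution" of the input attention block*: implemented
  as plain elementwise multiplication of the sigmoid gate.
* *Where the weight map applies*: to both the supervised and pseudo-label
  losses (both adopt the weighted CE + Dice combination).
* *What CutMix mixes*: pairs from the unlabeled pool, replacing the
  batch's unlabeled patch in place with probability `augment.cutmix.prob`;
  pseudo-labels are mixed with the same mask.
* *CBAM channel-MLP activation*: leaky ReLU (slope 0.01) rather than a
  hard ReLU — with the very narrow bottlenecks of small test networks a
  dead hidden unit would otherwise silence the branch permanently.
* *Normalization of inputs*: per-volume z-score.

## Problem sizes used by the tests and the demo

The demo benchmark trains on 32³ phantoms (2 labeled + 8 unlabeled, 3
held-out test volumes) with a width-4 network for 120 iterations — sizes
chosen so a full train/evaluate cycle runs in minutes on one CPU core while
still separating the full framework from its supervised-only baseline. The
64×64×48 default phantom grid and the published 112×112×80 patch protocol
remain available through the configuration for larger runs. Loss-formula
and metric oracles run on ≤ 12³ inputs where brute-force enumeration is
exact.

## Known limitations

* CPU-scale only: the autodiff engine is single-threaded per step and not
  meant for the published 6000-epoch protocols on real datasets.
* Binary segmentation is the tested path (`num_classes = 2`); the losses
  and network support more classes but the phantom generator does not.
* HDF5 container I/O is not provided (NIfTI and NRRD are); DICOM,
  resampling and registration are out of scope.
* The teacher's RNG state is not checkpointed, so a resumed run is not
  bit-identical to an uninterrupted one (each run is itself fully
  reproducible from its seed).
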