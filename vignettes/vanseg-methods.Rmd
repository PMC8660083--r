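---
title: "Voxel-wise adversarial segmentation of 3D vessels: models and methods"
author: "vanseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-wise adversarial segmentation of 3D vessels: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vanseg)
```

## The problem

Cerebrovascular segmentation of time-of-flight MR angiography (TOF-MRA) is
shaped by three properties of the data. First, vessel radii and voxel
intensities vary enormously within one subject: TOF imaging makes fast-flowing
blood bright, so large vessels are both thicker and brighter than distal
branches. Second, the classes are extremely imbalanced — typically well under
0.3 % of the voxels are vascular. Third, image noise of varying magnitude
degrades thin-vessel contrast. `vanseg` implements a segmentation pipeline
designed around these three properties: a convolutional generator with
*Fibonacci* feature aggregation, adversarial regularization by a *voxel-wise*
discriminator, class-imbalance-aware losses (soft Dice and focal loss), and
patch-based volumetric inference.

## The generator and Fibonacci connections

Within a convolutional block, *dense* connectivity feeds every layer the
concatenation of all previous layers' feature maps. This strongly regularizes
the block: gradients from a layer reach every predecessor directly, which
tends to make the learned channels similar. The *Fibonacci* connection keeps
feature reuse but weakens the regularization: layer $l$ receives only the
concatenation of the outputs of layers $l-1$ and $l-2$,

$$x_l = H_l([x_{l-1}, x_{l-2}]),$$

where $H_l$ is batch normalization, ReLU, then a $3^3$ convolution
(pre-activation order). The base cases are the natural Fibonacci seed: layer 1
consumes the block input, layer 2 the concatenation of the block input and
layer 1's output. For a block with uniform growth $g$ this gives input widths
$(c_{in},\, c_{in}+g,\, 2g,\, 2g,\, \dots)$ — `channelPlan()` computes them
for all three connection rules (`fibonacci`, `dense`, and the `linear`
ablation where each layer sees only its predecessor).

The default generator (`generatorConfig()`) is a deliberate reconstruction,
since only the connection rules, the "small kernels everywhere" principle,
the shallow-Fibonacci / deep-dense placement, the input-transition
convolution, and the deep-supervision branch are fixed by the method; exact
depths and widths are free parameters here:

* input transition: one $3^3$ convolution (16 filters) lifting the raw patch
  into feature space (this also buffers input noise from deeper layers);
* stage 1 (full resolution): Fibonacci block, 4 layers, growth 16;
* downsampling: stride-2 $3^3$ convolution;
* stage 2 (half resolution): dense block, 4 layers, growth 16;
* upsampling: kernel-2 stride-2 transposed convolution (exact ×2, no
  overlap artifacts);
* heads: $1^3$ classifier convolutions with a per-voxel softmax over the two
  classes. The deep-supervision head branches off stage 1 and is trained with
  the same composite loss at weight 0.5 (the weight is a free parameter; a
  constant between 0 and 1 is conventional for auxiliary heads).

Every piece is configurable; the tests deliberately run much smaller widths.

## The discriminators

The discriminator never sees a label map alone. Its input is the voxel-wise
product of a (noise-perturbed) raw patch with either the predicted foreground
probability map (fake branch, target 0) or the one-hot ground truth (real
branch, target 1); the noise guards against degenerate distributions when the
generator's output is nearly binary. Three receptive-field regimes are built
from the same `Ck` unit (convolution, batch norm, leaky ReLU of slope 0.2):

* **voxel** (`VAN`): every convolution has kernel 1 and stride 1, so each
  output score depends on exactly one input voxel — the adversarial signal
  enforces voxel-wise distribution consistency and is as dense as the
  segmentation itself;
* **patch**: `C64–C128–C256` with kernel 3 / stride 2, receptive field
  $15^3$;
* **volume**: `C64–C128–C256–C512–C512`, receptive field $63^3$.

`receptiveField()` implements the standard recursion
$RF = 1 + \sum_i (k_i - 1)\prod_{j<i} s_j$, and `receptiveFieldProbe()`
verifies it empirically on a built network by backpropagating from a single
central score and measuring the nonzero-gradient footprint. The probe builds
its network without batch normalization: in training mode batch statistics
couple all voxels, which would mask the architectural footprint; in the
trained networks themselves batch normalization uses running statistics at
inference, so the voxel discriminator's locality contract holds exactly
(a one-voxel perturbation moves exactly one score).

## Losses

With per-voxel class probabilities $p_{c,v}$ and one-hot targets $y_{c,v}$:

* **Cross-entropy** $-\sum_c \sum_v y_{c,v}\log(p_{c,v}+\varepsilon)$, a sum
  over voxels (additive in the patch).
* **Soft Dice** per class with squared denominators,
  $(2\sum_v p_v y_v + \varepsilon)/(\sum_v p_v^2 + \sum_v y_v^2 +
  \varepsilon)$, averaged over the two classes. The class average (rather
  than a class sum) is what keeps the coefficient in $[0,1]$ with value 1 at
  perfect overlap and 0 for disjoint binary maps; summing both classes would
  reach 2 at perfect overlap, contradicting the stated range, so the mean
  reduction is the default and `foreground_only` is offered as an
  alternative. Training minimizes $1 - DC$.
* **Focal loss** for the discriminator,
  $(1-p_t)^\gamma(-\log p_t)$ with $\gamma = 4$, where $p_t$ is the score
  assigned to the true target. This is the canonical modulation; the literal
  form $(1-S)^\gamma \cdot CE(S,T)$ (which fails to down-weight confident
  *negative* voxels) is available behind `focalForm = "printed"`.
* **Generator objective** $CE + (1 - DC) + w_{adv} \cdot A + w_{ds}(CE_{ds}
  + 1 - DC_{ds})$, where the adversarial term $A = -FL(S_{fake}, T{=}0)$
  (minimax form, default) decreases as the discriminator is fooled; a
  non-saturating form $+FL(S_{fake}, T{=}1)$ is available for stability.
  Focal terms are averaged per score voxel so $w_{adv}$ is comparable across
  discriminator kinds; batch reduction is the mean over patches (scale
  invariance in the batch size).
* **Discriminator objective** $FL(S_{fake},0)/V + FL(S_{real},1)/V$.

Smoothing uses $\varepsilon = 10^{-7}$ throughout. All gradients are
hand-derived and verified against central finite differences in the test
suite (relative error $<10^{-9}$ on full generator paths).

## Two-stage training

One training iteration has two stages: stage 1 updates only the generator
(the discriminator is frozen — its trainable parameters are untouched, though
its running statistics see the forward pass); stage 2 updates only the
discriminator, with the generator run in evaluation mode so its state is
bit-identical afterwards. The method's reference regime is the default: learning rate
$10^{-3}$ decaying by 10 % every 5 epochs, moment parameters $(0.9, 0.999)$,
40 epochs, all grid patches shuffled each epoch. "SGD with $\beta_1,
\beta_2$" is internally inconsistent (beta pairs parameterize adaptive-moment
methods), so the default optimizer is Adam with those betas; classical
momentum SGD is available via `optimizer = "sgd"`. The batch size is not
fixed by the method; the default is 2 patches. Discriminator-input noise is
fresh Gaussian with SD equal to 0.1 of the per-patch SD — the mechanism
(noise on the raw patch entering the discriminator) is prescribed, its
magnitude is not.

Checkpoints record parameters, optimizer state and RNG state at each epoch
start, so `resumeFit()` replays the remainder of a run exactly — the test
suite asserts bit-identical loss histories.

## Patch pipeline

Volumes are z-scored per volume with the population SD (`normalizeVolume`),
then tiled into overlapping cubic patches. For axis length $L$, patch $p$ and
overlap $o$ the patch count is $\lceil (L-p)/(p-o) \rceil + 1$ (1 if $L \le
p$); the grid covers $p + (n-1)(p-o)$ voxels and any shortfall is made up by
*trailing* zero-padding (the canonical tilings imply padding exists where the
grid does not fit; whether it was leading or trailing is not stated, so
trailing is chosen and recorded here). The canonical configurations — a
$1024 \times 1024 \times 92$ volume with $64^3$ patches and $(4,4,36)$
overlap giving $17 \times 17 \times 2 = 578$ patches, and $512 \times 512
\times 128$ with $(4,4,32)$ giving $9 \times 9 \times 3 = 243$ — are frozen
as exact tests.

Stitching takes hard labels (per-voxel argmax) and gives every voxel the
class with the most votes among covering patches. Ties go to the foreground
by default: thin-vessel recall is the stated clinical priority, and the tie
rule is configurable (`tie = "background"`). Patch order is row-major with x
fastest; coordinates are 0-based half-open intervals.

## Synthetic phantoms

The phantom generator (`phantomSpec()` / `generatePhantom()`) provides
study conditions with the statistical structure the method assumes, not a
physical flow simulation:

* piecewise-linear branching centerlines with circular cross-sections,
  rasterized by distance-to-centerline ≤ radius, entirely inside the volume;
* a monotone radius→intensity law (default linear, `200 * r`) standing in
  for the flow-rate/intensity link; partial-volume softening is a one-voxel
  linear ramp *outside* the hard label, so the per-tube mean intensity over
  labeled voxels equals the law's value;
* extreme imbalance: tubes are added, largest radius first, only while the
  foreground stays within `targetFgFraction` (default 0.003, matching the
  sub-0.3 % vascular fraction of clinical TOF-MRA); an infeasible budget is
  an explicit error;
* Gaussian background texture at a low level (default mean 20, SD 5);
* bit-exact determinism in (spec, seed).

Calibrated noise (`addGaussianNoise`) has SD equal to
`percent/100 × (max − min)` of the volume at the time it is added —
robustness is probed on test images, so the magnitude refers to the raw test
volume, pre-normalization. `computeSNR` uses the power-ratio definition
$10\log_{10}(\sum x^2 / \sum e^2)$ dB (no definition is printed where SNR
values appear, so the choice is recorded in the output's documentation) with
`Inf` as the zero-noise sentinel.

What the phantoms deliberately do **not** model: bias fields (none is
modeled, matching data where none was removed), flow artifacts, non-vascular
bright structures (skull, fat), or annotation noise. Passing tests on
phantoms therefore demonstrate that the machinery — losses, training loop,
patch pipeline, metrics — behaves as specified, not that clinical-grade
accuracy is achieved on real MRA.

## Evaluation

* `diceBinary`: $2|P \cap G|/(|P|+|G|)$; both-empty is defined as 1, one
  empty as 0.
* `surfaceDistances`: boundary voxels are foreground voxels with a
  background 6-neighbor (the volume border counts as background); distances
  are voxel-center Euclidean distances in mm with anisotropic spacing,
  computed by an exact Euclidean distance transform (per-axis lower-envelope
  sweeps). The test suite proves equality with brute-force all-pairs minima
  on random masks.
* `sasd` / `shd95`: symmetric mean and symmetric 95th-percentile of the two
  directed distance sets; percentiles use linear interpolation between order
  statistics (R type 7).
* `dtp`: Dice under p % noise as a percentage of noise-free Dice; exactly
  100 at zero noise for any deterministic model.
* `compareMethods`: one-tailed paired t-test ($H_0: \mu_1 = \mu_2$ vs
  $H_1: \mu_1 > \mu_2$, $\alpha = 0.01$ reported), Cohen's D in the paired
  $d_z$ convention (mean difference / SD of differences), and ICC(3,1)
  (two-way mixed, consistency, single measure). The paired-sample design
  names neither the Cohen's nor the ICC variant; these are the standard
  choices for paired per-volume scores and are recorded in the output.
  All-zero differences are reported as $t = 0$, one-tailed $p = 0.5$,
  $D = 0$ with a degenerate flag.

## Numerical choices and problem sizes

The conv-net engine is written in R with C++ kernels for the im2col/col2im
unfolding and the distance transform; convolutions become BLAS matrix
products. This keeps every computation inspectable and exactly reproducible
under a seed, at the cost of raw speed — the package targets method-level
verification and desk-scale experiments, not GPU-scale clinical training.
Consequently the vignette's and test suite's models are small on purpose:
capability checks train a tiny generator (transition 6, Fibonacci 3×6, dense
2×6, upsample 8) on $16^3$ patches of one $64^3$ phantom for a few hundred
steps, which reliably reaches held-out foreground Dice above 0.6 on an easy
high-contrast phantom (radii 1–2 mm, foreground ceiling 1 %). The
feature-diversity claim about Fibonacci versus dense blocks (higher
channel-wise SD of Fibonacci feature maps) is *not* asserted by the tests:
at these miniature scales the direction of the difference is seed-dependent,
so `diversityHistogram()` is verified on exact cases instead and the
comparison is left to full-scale experiments.

Other conventions: He-style weight initialization; batch-norm momentum 0.1
and $\varepsilon = 10^{-5}$; per-voxel argmax ties resolve to foreground
(consistent with the stitching tie rule); all randomness flows from
user-provided integer seeds through R's RNG.

## Known limitations

* No centerline extraction or topology-aware metrics (explicitly out of
  scope).
* No brain masking, bias-field handling, resampling or registration.
* Training at clinically meaningful sizes (64³ patches, widths of 16–64,
  hundreds of epochs) is impractical on a single CPU with this engine.
* The phantom's tube model does not produce near-touching parallel vessels,
  so the known failure mode of merging close vessels cannot be studied with
  it.

## A worked example

```{r example, eval = FALSE}
library(vanseg)

spec <- phantomSpec(seed = 1)          # 64^3, <=0.3% foreground
ph <- generatePhantom(spec)
ph$volume
mean(volValues(ph$label))              # realized foreground fraction

cfg <- trainConfig(mode = "generator_only", epochs = 18, batchSize = 4,
                   patchSize = 16, seed = 42)
gen <- generatorConfig(inFilters = 6, stages = list(
  list(connection = "fibonacci", nLayers = 3, growth = 6),
  list(connection = "dense", nLayers = 2, growth = 6)), upFilters = 8)
fit <- fitModel(list(ph), cfg, gen)

heldOut <- generatePhantom(phantomSpec(seed = 2))
pred <- predictVolume(fit$generator, heldOut$volume)
diceBinary(pred, heldOut$label)

sd_ <- surfaceDistances(pred, heldOut$label)
c(SASD = sasd(sd_), SHD95 = shd95(sd_))
```
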