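# vanseg

Voxel-wise adversarial segmentation of 3D cerebrovascular images in R.

`vanseg` is for researchers working on vessel segmentation of time-of-flight
MR angiography (TOF-MRA) and similar volumetric data, where three properties
dominate: large variation of vessel radii and intensities (TOF makes
fast-flowing blood bright, so thin vessels are dim), extreme class imbalance
(well under 0.3 % of voxels are vascular), and image noise. The package
implements, end to end and fully in R (with C++ kernels for the heavy
loops):

* **FiboNet-style generator** — a 3D conv net whose shallow stage uses
  *Fibonacci* feature aggregation, `x_l = H_l([x_{l-1}, x_{l-2}])` (each
  layer concatenates the previous *two* layers only, weakening dense
  connectivity's regularizing effect to diversify features), a dense block
  in the deep stage, and a deep-supervision branch;
* **voxel-wise adversarial network (VAN)** — a discriminator built entirely
  of kernel-1/stride-1 layers so each output score depends on exactly one
  input voxel; patch-level (`C64–C128–C256`, receptive field 15³) and
  volume-level (`C64–…–C512`, 63³) discriminators for comparison;
* **class-imbalance losses** — generator: cross-entropy + (1 − soft Dice),
  where per-class Dice uses squared denominators
  `2Σpy / (Σp² + Σy²)`; discriminator: focal loss `(1−p_t)^γ·CE`, γ = 4.
  Discriminator inputs are voxel-wise products of a noisy raw patch with
  the probability map (fake) or ground truth (real);
* **two-stage training** — alternating generator/discriminator updates,
  lr 0.001 decaying 10 % every 5 epochs, betas (0.9, 0.999), 40 epochs;
  exact checkpoint/replay;
* **patch pipeline** — per-volume z-scoring, overlapping 64³ tiling with
  per-axis counts `ceil((L−p)/(p−o))+1`, majority-vote stitching;
* **evaluation** — Dice, symmetric average surface distance (SASD) and
  95th-percentile Hausdorff (SHD95) in mm from an exact anisotropic
  Euclidean distance transform; noise-robustness sweeps with drop-to
  performance `DTP = DC_p/DC_0 × 100 %`; paired one-tailed t-tests with
  Cohen's D and ICC;
* **synthetic vascular phantoms** — branching tubes with radius-linked
  intensity, sub-0.3 % foreground, calibrated Gaussian noise
  (SD = percent/100 × image range), for testing the machinery without
  clinical data.

See `vignettes/vanseg-methods.Rmd` for the models, the assumptions, and
every numerical convention.

## A worked example

Generate an easy synthetic phantom, train a miniature generator-only model
(CE + Dice) for 288 steps, and evaluate on a held-out phantom:

```r
library(vanseg)

spec <- phantomSpec(shape = c(64, 64, 64), targetFgFraction = 0.01,
                    radiusRange = c(1.0, 2.0),
                    intensityLaw = function(r) 400 * r,
                    backgroundTextureSd = 2, nTrees = 2, branchDepth = 2,
                    seed = 11)
ph <- generatePhantom(spec)
ph$volume
#> Volume3D 64x64x64, spacing 0.5x0.5x0.6 mm
#>   intensity range [11.45, 707.8]
ph$label
#> LabelVolume 64x64x64, spacing 0.5x0.5x0.6 mm
#>   intensity range [0, 1]
#>   foreground fraction 0.00529

cfg <- trainConfig(mode = "generator_only", epochs = 18, batchSize = 4,
                   patchSize = 16, seed = 42)
gen <- generatorConfig(inFilters = 6, stages = list(
  list(connection = "fibonacci", nLayers = 3, growth = 6),
  list(connection = "dense", nLayers = 2, growth = 6)), upFilters = 8)
fit <- fitModel(list(ph), cfg, gen)

heldOut <- generatePhantom(phantomSpec(shape = c(64, 64, 64),
  targetFgFraction = 0.01, radiusRange = c(1.0, 2.0),
  intensityLaw = function(r) 400 * r, backgroundTextureSd = 2,
  nTrees = 2, branchDepth = 2, seed = 12))
pred <- predictVolume(fit$generator, heldOut$volume)
diceBinary(pred, heldOut$label)
#> [1] 0.6446

sd_ <- surfaceDistances(pred, heldOut$label)
c(SASD = sasd(sd_), SHD95 = shd95(sd_))
#>  SASD SHD95
#> 0.4728 0.9880
```

The foreground fraction (0.53 %) realizes the extreme imbalance of
cerebrovascular data; a three-minute CPU training of a 6-filter model
already recovers the vasculature of an unseen phantom with Dice 0.64 and
sub-voxel average surface error (0.47 mm at 0.5 mm spacing). The reference
patch-grid arithmetic is reproduced exactly:

```r
g <- planPatchGrid(c(1024, 1024, 92), c(64, 64, 64), c(4, 4, 36))
gridCounts(g)                             # 17 17  2
nPatches(g)                               # 578
receptiveField(discriminatorConfig("patch"))   # 15
receptiveField(discriminatorConfig("volume"))  # 63
```

## Command line

A thin launcher over `runCli()` is installed at
`system.file("cli", "vanseg", package = "vanseg")`:

```sh
vanseg phantom-gen --shape 64,64,64 --fg-fraction 0.003 --seed 1 --out-dir ph/
vanseg split --in ph/phantom.nii.gz --patch-size 64,64,64 --overlap 4,4,36 --out-dir patches/
vanseg train --config cfg.yaml --data-dir data/ --out-dir run/
vanseg predict --model run/model.rds --in vol.nii.gz --out pred.nii.gz
vanseg evaluate --pred-dir preds/ --gt-dir gts/ --out-dir eval/
vanseg noise-sweep --model run/model.rds --data-dir data/ --percents 0.1,0.5,1,1.5,2
vanseg stats --method-a a.csv --method-b b.csv --out stats.json
vanseg rf-calc --layers 3x2,3x2,3x2        # prints 15
```

Every run writes its resolved configuration next to its outputs, and all
randomness flows from the seed options.

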