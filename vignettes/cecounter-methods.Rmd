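---
title: "Counting cultured corneal endothelial cells with a semi-supervised U-Net"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting cultured corneal endothelial cells with a semi-supervised U-Net}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Human corneal endothelial cells (HCECs) expanded in vitro for cell therapy
must be counted repeatedly during manufacturing. The conventional instrument
— a hemocytometer — requires detaching the cells, so counts are only
available at passaging. Phase-contrast micrographs, by contrast, are acquired
routinely and non-destructively. `cecounter` implements a pipeline that
turns such micrographs into cell counts: a small U-Net classifies every
pixel as *cell center* versus *background*, connected components of the
thresholded probability map become detected centers, and detected centers
divided by the imaged field area give a density (cells·mm⁻²) that
extrapolates to a total cell number for the culture vessel.

Because manual annotation of cell centers is expensive, training is
semi-supervised in two stages:

1. **Initial model** — train on a small, manually annotated pool; select the
   epoch with minimal validation loss.
2. **Cell count model** — use the initial model to pseudo-label a larger
   unlabeled pool, correct the pseudo-labels (in production, by a human; here
   this correction is simulated), merge with the labeled pool, re-split,
   augment fourfold by mirroring, and retrain.

## The model

The classifier is a U-Net: an encoder of `depth` levels (two 3×3
convolutions + ReLU per level, 2×2 max-pooling between levels) mirrored by a
decoder (2× nearest-neighbour upsampling followed by a 2×2 convolution, skip
concatenation with the encoder feature map, two 3×3 convolutions), closed by
a 1×1 convolution to two classes and a per-pixel softmax. All convolutions
use same-padding, so probability maps align pixel-for-pixel with the input —
whole images go in, whole maps come out, with no tiling arithmetic. The loss
is per-pixel cross-entropy (optionally foreground-weighted), optimized by
Adam, one image per step. No deep-learning framework is available in the
target environment, so forward, backward and the optimizer are implemented
in compiled code (im2col + BLAS matrix products); the backward pass is
verified against finite differences in the test suite.

Point annotations are turned into a trainable segmentation target by
stamping a binary disk (default radius 3 px at working resolution) at each
center; overlapping disks merge. Detection inverts this: threshold the
foreground probability at 0.5, label connected components (8-connectivity),
drop components under 2 px, and take each component's probability-weighted
centroid.

Two numerical choices are worth noting. First, the softmax subtracts the
per-pixel maximum logit and the loss clamps probabilities at 1e-12, so any
finite input yields a finite loss; the trainer still aborts on non-finite
values as a data-level guard. Second, by default the final-layer bias is
initialized to the log class prior computed from the training masks
(`init_bias_prior`), so early epochs are not spent learning the large
foreground/background imbalance.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `resize_factor` | 0.25 | working resolution (1392×1040 → 348×260) |
| `gamma` | 0.8 | gamma correction before contrast stretch |
| `contrast_stretch` | (1, 99) | percentile stretch; (0, 100) disables it |
| `boundary_highlight_weight` | 0.5 | unsharp-mask weight accentuating dark borders |
| `disk_radius_px` | 3 | label disk radius at working resolution |
| `prob_threshold` | 0.5 | detection threshold on the foreground class |
| `match_radius_px` | 10 | max accepted prediction–truth distance (px, working) |
| `um_per_px` | 0.645 | acquisition pixel pitch (µm); a configurable default, not ground truth |
| Adam `lr` | 1e-3 | with β = (0.9, 0.999), one image per step |

The upstream workflow names its preprocessing operations (resize by ¼, gamma
correction, contrast adjustment, boundary highlighting, histogram
flattening) but none of their parameters, and neither its pixel pitch nor
its label-target construction, matching rule, or averaging scheme is
recorded. Every value above is therefore this package's own calibration, and
absolute densities depend on the pitch the user supplies. The printed
working size "348 × 360" of the source workflow is arithmetically
inconsistent with a uniform ¼ resize of 1392 × 1040 and is treated as a typo
for 348 × 260.

Two readings of "augmented by inverting the images" were possible: intensity
inversion or geometric mirroring. The package mirrors: the stage-2
bookkeeping (2341 training images → 9364) matches {identity, horizontal
mirror, vertical mirror, 180° rotation} exactly, and intensity inversion
would destroy the phase-contrast polarity (dark borders, bright interiors)
the classifier relies on.

Epoch selection is mechanized as the argmin of the validation loss with ties
broken toward the earlier epoch — the defensible automatic counterpart of
selecting an epoch by visually inspecting loss curves.

## Evaluation

Predicted and reference centers are matched one-to-one by a greedy
globally-nearest-first rule with a deterministic tie-break; the test suite
checks it against exhaustive optimal matching on small unambiguous
instances. Precision, recall and F are computed per image and
macro-averaged, with 95% percentile-bootstrap confidence intervals over
images (2000 resamples, seeded). Macro averaging was chosen because the
upstream report's aggregate F values are inconsistent with the harmonic mean
of its aggregate precision and recall — only a per-image averaging scheme
permits that, and the bootstrap-over-images CI construction follows
naturally. An image with neither references nor predictions scores
P = R = F = 1 and is flagged; an image with references but no predictions
(or vice versa) scores 0 on the undefined ratio.

## The synthetic generator: what it emulates, and what it does not

No public HCEC phase-contrast dataset exists, so the package ships a
generator whose scenes stand in for micrographs. A confluent endothelial
monolayer is a mosaic of convex polygonal cells; the generator renders a
Voronoi tessellation seeded at known centers: interiors shade from bright at
the seed (200) toward the ridge (80), ridge pixels within a ~2 px band drop
to 30% of the local interior intensity (the dark borders), the band just
inside brightens by a configurable halo factor, per-cell brightness varies
with the radius CV, and i.i.d. Gaussian noise (σ = 6 gray levels) is added
before 8-bit quantization. Density regimes default to 500 / 1500 / 3000
cells·mm⁻² (low / middle / high), spanning subconfluent to confluent
cultures.

Cell counts per field are Poisson-drawn from the target density × field
area, so density estimates inherit realistic sampling error. Centers are
placed on a jittered hexagonal lattice: a random subset of lattice sites,
each jittered uniformly within a disk sized so the pairwise minimum distance
stays at 0.8 × the mean cell diameter by construction. A pure
dart-throwing ("Poisson-disk") scheme was rejected because it jams near
packing fraction 0.55, below what a confluent mosaic requires (~0.64).
When a Poisson draw is more crowded than the nominal configuration, the
spacing floor follows the *realized* mean cell diameter (field area /
count) — crowded fields simply have smaller cells — while infeasibility
(nominal packing fraction > 0.9, essentially beyond hexagonal close packing)
is judged on the target configuration so that a given spec either always
renders or always errors, independent of the draw.

The generator does **not** emulate: phase-contrast optics (no point-spread
function or shade-off), illumination gradients, debris, fibroblastic
morphology change, out-of-focus fields, or annotation noise. A green test on
synthetic data therefore establishes that the pipeline's machinery —
training, pseudo-labeling, detection, matching, quantification — works end
to end and that the network can learn this class of appearance; it does not
establish performance on real micrographs, which depends on appearance
factors the generator deliberately omits. At low cell counts the jittered
lattice is also more regular than real subconfluent cultures.

## The scaled-down benchmark

The source experiment (3098 images, 30-epoch training) is emulated at desk
scale by `run_benchmark()`: 200 labeled + 400 unlabeled + 80 test scenes of
256×256 px (64×64 at working resolution), regimes in equal thirds, a
depth-2 / 8-channel U-Net, up to 8 epochs per stage (both stages train by
the same method with the same budget, as upstream), perfect correction
policy. The stage-1 labeled pool splits ~77:23 into train and
validation and the merged stage-2 pool ~76:24, mirroring the source ratios
(402:121 and 2341:757). The label disk radius is 2 px rather than the
package default 3 because at the high-density regime adjacent centers sit
~6.4 px apart at working resolution, and radius-3 disks (diameter 7) would
fuse adjacent training targets *by construction*; this was fixed from that
geometry before any benchmark was run. With perfect correction the stage-2
labels equal ground truth, so the semi-supervised stage reduces to
supervised training on the full pool — the mechanism by which the original
workflow's F improved — and the benchmark asserts the same direction:
cell-count-model F ≥ initial-model F at fixed seeds.

The overfit sanity fixture (10 sparse scenes at 150 cells·mm⁻², depth-2 /
base-4 net, learning rate 3e-3) memorizes to a training loss below 0.05
within 200 steps; sparse fields are used because at that budget most
residual loss sits on ambiguous disk-edge pixels, whose share shrinks with
density.

## Known limitations

- Absolute densities are calibration-dependent: the pixel pitch of the
  source images is unknown, so 0.645 µm/px is a default, not ground truth.
- The simulated correction step models human revision as independent
  Bernoulli fixes; real annotators make correlated errors.
- Training is single-image Adam on one CPU; no schedules, batching, or GPU
  support. The benchmark network is deliberately small.
- Probability-map PNGs are written 8-bit (the available PNG writer does not
  emit 16-bit); center CSVs carry full precision, so downstream metrics are
  unaffected.
- Near the packing-feasibility edge (nominal fraction just below 0.9) the
  lattice may still fail to seat a very unlucky draw; the supported regimes
  sit far from that edge.
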