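---
title: "Inpainting detector gaps in 2D X-ray scattering images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inpainting detector gaps in 2D X-ray scattering images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scattergap)
```

## The problem

Tiled photon-counting detectors record 2D small- and wide-angle X-ray
scattering (SAXS/WAXS) patterns with dead stripes between sensor modules.
On a PILATUS3 2M — three columns of eight modules on a 1475 × 1679 px frame
— seven 17 px horizontal gaps and two 7 px vertical gaps cut every frame
into 24 islands. (The detector's documentation is ambiguous about the
vertical gap width; only 7 px makes the module width integral,
3·487 + 2·7 = 1475, so `pilatus3_2m()` defaults to 7 and exposes the width
as a parameter.) Traditional azimuthal-integration workflows simply mask
these pixels, but downstream machine-learning tasks — automated sample-type
identification, orientation determination, latent-space indexing — work on
the whole image and are disturbed by the missing stripes. `scattergap`
reconstructs (*inpaints*) the gap pixels.

Horizontal gaps admit real ground truth when a dataset is acquired twice
with a vertical detector translation; vertical gaps never do. The package
therefore manufactures vertical-gap supervision by data augmentation (below)
and evaluates the two gap classes separately.

## Working resolution and pre-processing

Frames are resampled to a square working resolution (512 × 512 reference)
with separable Catmull–Rom bicubic interpolation, log-scaled with
`log(1 + x)` and min–max normalised per frame to [0, 1]
(`preprocess_frame()`). `log1p` rather than a bare logarithm keeps zero
(masked and empty pixels) fixed and finite; per-frame rather than global
normalisation makes every frame fill the unit range the networks expect,
at the cost of absolute-intensity comparability between frames — acceptable
because all metrics compare a prediction with its own frame's truth. The
gap mask is rescaled by rounding each gap rectangle's edges to the nearest
integer with a floor of 1 px (`rescale_mask()`), so the thin 7 px vertical
gaps survive downscaling (at 512 they become 2 px, cols [169, 171) and
[341, 343)).

## Gap-grid augmentation

`crop_strips()` cuts a working frame of side *S* into 7 overlapping column
bands of width *S*/4 at offsets that are multiples of *S*/8 (512 × 128
strips with 64 px overlap at the reference size). The 4 strips that touch a
true vertical gap carry no ground truth there and are discarded; each of
the 3 survivors receives one artificial vertical gap
(`insert_artificial_gap()`) drawn uniformly from the local start columns at
which the true vertical gaps sit inside the discarded strips, plus a
sentinel "no gap" draw (at 512: {−1, 21, 41, 85, 105}, width 2,
derived automatically from the mask by `artificial_gap_candidates()`).
Placing artificial gaps only at true-gap-consistent positions means the
network trains on exactly the column geometry it must fill at inference
time. Every frame therefore contributes exactly 3 training pairs: 4641
frames yield 13 923. Each survivor is augmented once per dataset pass
rather than re-randomised every epoch; the draw is seeded and the
augmented set is reproducible.

At inference, all 7 strips of a frame pass through the network and
`stitch_strips()` recombines them by arithmetic overlap averaging, which
suppresses patch-edge artefacts; on unmodified strips stitching inverts
cropping at machine precision.

## The four networks and the baseline

All four architectures are shape-preserving 1-channel maps built from 3 × 3
zero-padded convolutions on compiled kernels, with linear outputs (targets
live in [0, 1] but no final activation or clamp is applied during training;
clamping would hide calibration errors from the loss). No normalisation
layers are used anywhere — none are needed at this scale, and they would
change the parameter counts below.

* **Convolutional autoencoder** (`build_autoencoder()`): conv/ReLU/max-pool
  encoder stages (32 base channels doubling per stage, depth 2 reference),
  a purely spatial latent map, and a decoder of alternating convolutions
  and 2 × 2 stride-2 transposed convolutions. Blind: no mask input.
* **Tunable U-Net** (`build_tunet()`): depth, base channels and channel
  growth rate are free; channels at level *d* are
  `round(base · growth^d)` (half-up, so fractional growth rates like 1.5
  and 2.5 work). Two conv+ReLU per level, max-pool contraction, transposed
  conv expansion with channel-wise skip concatenation, 1 × 1 output conv.
  Blind.
* **Partial-convolution U-Net** (`build_partialconv_unet()`): the same
  topology, but every convolution sees only valid pixels and renormalises
  by `kernel size / valid count`; a pixel becomes valid once any valid
  pixel enters its window, so the mask's valid region grows monotonically
  layer by layer. The mask stream is max-pooled downward and
  nearest-upsampled upward; after a skip concatenation the two branch masks
  are merged with an elementwise maximum (the branches carry one
  single-channel mask each; the maximum preserves both the
  full-mask-equals-dense-U-Net reduction and the monotone-growth
  guarantee). Out-of-frame window cells count as valid in the
  renormalisation, so under a full mask every layer reduces *exactly* to a
  zero-padded dense convolution, borders included. Not blind:
  `net_forward()` requires the validity mask.
* **Mixed-scale dense network** (`build_msdnet()`): every layer computes
  one channel by a 3 × 3 convolution over the input plus all previous
  layer outputs, with dilation cycling `((i−1) mod max_dilation) + 1`; a
  1 × 1 convolution over the full stack forms the output. With width 1 the
  trainable count is exactly `4.5 d² + 6.5 d + 2` (9·i weights + 1 bias at
  layer i, d+2 output parameters): 11 577 (0.012 M) at 50 layers, 181 302
  (0.181 M) at 200 — two to four orders below the U-Nets.

The non-learned baseline (`biharmonic_inpaint()`) fills each gap pixel with
the discrete biharmonic extension of the surrounding data: the 13-point
∇⁴ stencil (20 / −8 / +2 / +1) is assembled over all gap pixels as one
sparse system with clamped boundary values and solved by a cached sparse LU
factorisation; out-of-frame stencil references are mirrored at the frame
edge. Constants and affine ramps are biharmonic, so they pass through
interior gaps exactly (the mirror boundary perturbs exactness only for
gaps touching the frame edge). A single global solve rather than a
per-component solve is used because the horizontal and vertical bands of a
detector mask intersect and form one connected region anyway, and it
avoids order dependence when two gap regions pass within the stencil
radius of each other.

## Training recipe

`train_inpainter()` minimises plain L1 loss (no adversarial term, no extra
regularisation) with ADAM (default moments) under a step schedule: initial
rate 10⁻³ dropped tenfold every `lr_step` epochs — reference schedule
100/300, with 60/180 for the 200-layer dense-dilated variant. The loss is
computed over all pixels of the target strip, not gaps only: the identity
part of the task stabilises training, and evaluation composites
(`composite_non_gap()`) discard non-gap predictions anyway; a
`loss_on_gaps_only` switch provides the alternative. Validation holds out
a fraction of *parent images* (10 % default) so sibling strips never
straddle the split, and the best-validation weights are returned. All
shuffling and splitting is seeded; two runs with one configuration are
bitwise identical.

Evaluation is two-track (`evaluate_inpainter()`): horizontal gaps are
scored on stitched full-frame inference against the gap-filled truth;
vertical gaps on the augmented evaluation pairs, restricted to the
artificial gap columns. Both tracks report the gap-pooled mean absolute
error and the pooled product-moment correlation (one coefficient per
method and class; per-image L1 is also returned), plus the mean truth
intensity over the gaps as context. A zero-variance pool yields `NA`
correlation with a warning, never a silent 0.

## Synthetic data

The beamline library this methodology was developed against is not
redistributable, so `simulate_pairs()` generates the study conditions: a
radial power-law background, 1–4 Gaussian-profile Debye–Scherrer rings
with optional azimuthal modulation, localised Gaussian peaks, a central
beamstop shadow and Gaussian read noise (σ in 0.005–0.02 of the
normalised range). Three stress cases appear with set probabilities:
a peak wholly inside a horizontal gap band, a peak triplet hugging the
beamstop, and a fourfold-symmetric peak quadruplet. The generator renders
natively at 1475 × 1679 and resizes when the full pre-processing path is
wanted, or directly at the working size for speed. Gaussian rather than
Poisson counting noise is a deliberate simplification — the evaluation
metrics are insensitive to the choice, and photon-level calibration is out
of scope, as are q-space calibration and real form/structure factors. What
passing tests on this generator shows is that the pipeline's mechanics and
the relative ordering of methods behave as expected; absolute errors on
real beamline data are not predicted by it.

## Latent-space analysis

`train_embedding()` fits a small reconstruction autoencoder (three
conv/pool stages, global average pooling, dense projection to exactly 200
dimensions) — deliberately a separate, simpler network from the inpainting
autoencoder, since its only job is a comparable embedding. The masked,
ground-truth and inpainted image sets are embedded with identical
configuration and seed; `neighbor_rank_curve()` reports the mean Pearson
correlation between an image and its rank-r Euclidean latent neighbour
(computed on the *masked* pixel vectors for every space, so gap pixels
offset all spaces equally), and `knn_overlap()` the percentage overlap of
100-nearest-neighbour sets against the ground-truth space. Conventions the
analysis fixes: the self is never its own neighbour (rank 1 is the nearest
distinct image), and distance ties break by ascending image id, making
every ordering reproducible.

## Problem sizes used in the shipped checks

The test suite exercises the full pipeline at reduced scale, chosen as the
smallest sizes at which the scientific orderings are expressed: a
256 × 256 working resolution (horizontal gaps 2–3 px, vertical 1 px after
rescaling; survivors at offsets {0, 96, 192} with candidates
{−1, 10, 21, 42, 53}) and 200 synthetic frames split 160/40. The trained
models are a 16-layer dense-dilated network (30 epochs, rate drops every
12) and a depth-3, base-4 U-Net (18 epochs, drops every 6) — the
reference schedule's shape, thirds, at desk scale. Two choices depart from
the full-scale recipe and deserve a word. First, the benchmark trains with
the gap-restricted loss switch: with the sign-valued gradient of L1, the
~91 % of strip pixels where the task is the identity contribute gradients
of the same magnitude as the gap pixels, and at a few hundred strips the
networks spend their entire short budget polishing the identity map;
restricting the loss support to the invalid pixels matches the training
signal to the gap-restricted evaluation. (At full scale, with 13 923
strips and 300 epochs, the whole-strip loss default is the right setting
and remains the package default.) Second, batches of 2 rather than the
published per-architecture batch sizes: the epoch budget caps the number
of ADAM updates, and smaller batches buy more updates from the same
number of sample visits. Under this recipe both trained networks reach a
horizontal-gap L1 at or below the biharmonic baseline on the seeded
benchmark — a demanding bar at this scale, since with 2–3 px rescaled
gaps the clamped biharmonic interpolant sits within a few thousandths of
the irreducible noise floor. The latent suite embeds all 200 frames at a
64 × 64 encoder resolution (6 epochs) and uses the reference k = 100.
The exact-count checks (7 strips, 3 survivors, 13 923 pairs from 4641
frames, 24 modules, parameter counts) run at full size, since they are
cheap.

## Known limitations

* Only rectangular full-width/full-height gap bands are modelled; custom
  beamstop shapes and per-pixel bad-pixel maps would need the
  partial-convolution route with an arbitrary mask, which the layer
  supports but the mask container does not.
* A feature wholly inside a gap with no trace outside it is unrecoverable
  by any method here — the suite asserts this as a property rather than
  pretending otherwise.
* The networks train on CPU through compiled kernels; they are sized for
  method comparison, not for production-scale sweeps of the full published
  grids (the `sweep` subcommand runs a reduced grid).
* Fourfold symmetry is not exploited by any model (strips see only a
  column band), so symmetric peak sets are reconstructed only as well as
  their local context allows.
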