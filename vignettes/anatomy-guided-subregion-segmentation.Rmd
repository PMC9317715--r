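---
title: "Anatomy-guided segmentation of pancreatic subregions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anatomy-guided segmentation of pancreatic subregions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The pancreas is a curved, J-shaped ("hockey stick") organ conventionally
divided into three anatomical subregions — head, body and tail — that
differ in tumor biology, symptoms, drug response and prognosis, which makes
region-resolved analysis of CT scans clinically valuable. The difficulty is
that nothing in the image marks the internal head/body/tail boundaries:
there is no edge or intensity change at the transitions, so a purely
appearance-driven segmenter has little to learn from. What *is* reliable is
anatomy: the three parts always appear in the order head–body–tail along
the organ, and they occupy roughly stable proportions of its length
(about 40%, 33% and 26%).

`pancseg` implements a pipeline that exploits exactly this structure. It
assumes the whole pancreas has already been delineated (whole-organ
segmentation is a solved, separate problem) and splits the given mask into
the three subregions by combining

1. an **anatomical prior**: a naive Bayes model over two normalized
   geometric features of each voxel, producing a per-voxel soft label
   (three class probabilities), and
2. an **appearance model**: a compact 3D encoder–decoder segmentation
   network producing its own probability map,

fused voxel-wise by probability multiplication and renormalization.

## Geometric features

Let the pancreas mask be a single 26-connected voxel component. All
distances are *geodesic*: shortest paths on the 26-connected voxel graph
constrained to stay inside the mask, with Euclidean step lengths in mm.
We chose the mask-constrained rather than straight-line distance because
the organ is curved: a straight chord between head and tail exits the
organ, and a within-organ length is the quantity the anatomical fractions
refer to. (A straight-line variant is available via
`alpha_feature(metric = "euclidean")` for comparison.)

* `y_f`, the **head endpoint** — with training labels, the head voxel
  geodesically farthest from every body/tail voxel. Without labels
  (inference), the organ's pseudo-diameter is found by the standard double
  sweep (farthest voxel from an arbitrary start, then farthest from that),
  and the head end of the two is chosen by laterality: on the axial view
  the head sits on the patient's right, i.e. at the low end of the first
  axis under the default orientation (`head_axis`/`head_side` make this
  explicit and configurable). Argmax ties are broken by the smallest
  (x, y, z) index so results are deterministic.
* `l`, the **organ length**: the maximum geodesic distance from `y_f`,
  attained at the far endpoint `z_f`.
* `alpha' = d(y_f, x) / l` — the **length fraction** of voxel `x`,
  clipped to [0, 1]. Small near the head, large in the tail.
* `beta'` — the **swept-volume fraction**: the number of pancreas voxels
  geodesically nearer to `y_f` than `x` (inclusive), divided by the total
  pancreas voxel count `A`. The phrase "voxels lying between the head
  start and `x`" is ambiguous for a curved organ; the cumulative
  definition is well defined for any shape, reduces to the axis-aligned
  count on a straight tube, and makes `beta'` co-monotone with `alpha'`
  by construction (this is deliberate: `beta'` encodes the *volume*
  profile — a thick head sweeps volume faster per unit length than the
  thin tail). An axis-aligned bounding-box count is available as
  `beta_feature(method = "bbox")`.

Both features are dimensionless fractions, so models fitted on one cohort
transfer to scans with different voxel spacing and organ size.

## The naive Bayes soft label

For each subregion `s` the model fits univariate Gaussians to `alpha'` and
`beta'` over all training voxels pooled across cases (sample mean, unbiased
sd). The per-voxel posterior is

    P(s | x)  proportional to  N(alpha'; mu_a[s], sd_a[s]) p(s)
                             * N(beta';  mu_b[s], sd_b[s]) p(s)

renormalized over the three classes. Priors default to equal — the
per-feature prior is applied exactly once per feature, and because the
posterior is renormalized per voxel, any constant prior cancels; the knob
exists for completeness and for ablation (a zero prior removes a class).

Numerical choices: densities are evaluated in log space and normalized
with log-sum-exp, so voxels far in a distribution tail cannot underflow to
0/0; standard deviations are floored at `sigma_floor = 1e-3` (fraction
scale) so a degenerate subregion (few voxels, identical values) cannot
produce a density spike that overwhelms the other classes. With ordered
class means and co-monotone features, the argmax of the posterior along
the organ is a contiguous head block, then body, then tail — the model
cannot interleave classes, and in particular head/tail confusion requires
probability mass to jump across the body's territory, which the Gaussian
ordering makes practically impossible.

## The segmentation network and fusion

The appearance model is a compact 3D encoder–decoder: 3x3x3 convolutions
with ReLU, 2x average-pool down-sampling, nearest-neighbour up-sampling
with skip concatenation, and a 1x1x1 three-class softmax head. The default
configuration uses three resolution levels; the desk preset (sized for
32-voxel phantoms on one CPU) uses two levels and four base channels. The
input is the normalized intensity volume, by default concatenated with the
three Bayes soft-label channels; a switch (`input_bayes = FALSE`)
restricts the input to the image alone.

Forward and backward passes are implemented directly on R arrays
(shift-based im2col plus BLAS matrix products), which keeps the code
dependency-free, exactly reproducible for a fixed seed, and fast enough at
desk scale. Average pooling was preferred over max pooling because its
adjoint is linear, keeping the hand-derived backward pass simple and
exactly verifiable; the gradient of every layer is checked against central
finite differences in the test suite.

Training minimizes, per case, the mean over classes of (1 − soft Dice)
plus the focal loss (focusing exponent `gamma = 2`, no alpha-balancing),
mixed 1:1, evaluated **on the fused map**: in every epoch the network's
softmax map `Y` is multiplied voxel-wise with the case's Bayes map `X` and
renormalized, `Yhat = normalize(Y * X)`, and the loss and gradients are
taken through `Yhat`. Voxels where all three products vanish fall back to
the uniform distribution (this can only happen when both models assign a
class zero probability; the fallback avoids NaNs and receives zero
gradient). Optimization is Adam at learning rate 1e-4 with mini-batches of
2 whole cropped volumes; the checkpoint with the best mean training Dice
is kept, and a maximum epoch count (500 by default, 15 in the desk preset)
bounds the run. Setting `fusion = FALSE` reproduces the plain-network path
bit-for-bit — this is the ablation baseline, and with a uniform `X` the
fused path is algebraically identical to it (a property the tests assert).

The loss is computed over pancreas voxels only. Background voxels carry no
gradient and predictions outside the mask are forced to background, which
matches the problem statement: the organ outline is given, only its
interior is in question.

## Preprocessing

Volumes are cropped to the tight bounding box of the mask plus a
configurable margin (8 voxels by default; the original fixed-resolution
resampling of the source data is dataset-specific and deliberately not
reproduced — the network pads each case to a multiple of the pooling
factor internally instead). Non-pancreas voxels are set to exactly 0 and
pancreas intensities are min–max scaled to [0, 1] over mask voxels only.
A constant-intensity pancreas maps to all zeros rather than erroring,
which keeps degenerate synthetic fixtures usable. Masks with several
26-connected components are a hard error by default (`keep_largest =
TRUE` opts into keeping the dominant component), since the model assumes
one whole pancreas. Normalization is idempotent and invariant to affine
intensity rescaling, and the crop records its offset so label volumes can
be placed back on the original grid exactly. Whether normalization runs
before or after cropping is immaterial because its statistics use
pancreas voxels only; the implementation crops first.

## The phantom generator

Real CT cohorts with subregion labels cannot ship with a package, so the
generator builds labeled stand-ins that preserve exactly the properties
the method relies on. A cubic Bezier centerline (straight, ~90-degree "J",
or ~160-degree "U" preset — the latter emulating the irregular morphology
where such methods degrade) is swept with a linearly tapering radius;
labels are assigned by arc-length fraction with defaults 0.40/0.33/0.26;
intensities are a per-region mean plus Gaussian noise over a soft-tissue
background, produced in raw arbitrary units so the phantoms must pass
through the real preprocessing path. Tube proportions follow the organ's
stated anatomy (anteroposterior diameter 1–3 cm against 12–15 cm length):
at the default 32-voxel grid the head radius is 3 voxels tapering to 1.5,
about 0.11 of the tube length. The dataset generator jitters size
(+-30%), length fractions (+-5%), noise (+-20%) and centerline control
points per case and records every resolved spec in a manifest; an optional
tumor-like perturbation changes local texture without touching the mask.

What the phantoms do *not* emulate: CT physics (no beam hardening, no
neighbouring organs), realistic texture heterogeneity, mask errors from an
upstream whole-organ segmenter, and surgical or inflammatory anatomy
changes. Green tests on phantoms therefore demonstrate that the
*mechanics* of the method (features, Bayes calibration, fusion, training)
are correct and that the pipeline is deterministic — not that the reported
Dice levels transfer to patient data.

## Problem sizes and study conditions

The package's own evaluation runs at desk scale: 8 phantoms on 32-voxel
grids, 4-fold cross-validation, the 2-level/4-channel network for 15
epochs per fold — a complete run takes a few minutes on one CPU, and the
same configuration backs `scripts/acceptance.R`. The full-size preset
(3 levels, 8 channels, 500 epochs) mirrors the configuration a real cohort
would use but is not exercised by the tests. The Bayes quality gate in the
acceptance suite (per-class Dice of at least 0.85 per fold for the
Bayes-only baseline) is a property of this phantom cohort, chosen as a
regression tripwire rather than a clinical claim.

## Known limitations

* The method presumes a whole pancreas; post-surgical (resected) anatomy
  violates the length-fraction prior and is out of scope.
* Inference-time head detection relies on the laterality convention; a
  scan whose orientation metadata is wrong will silently swap head and
  tail (the `head_axis`/`head_side` options are the escape hatch).
* The subregion boundaries are genuinely ambiguous even for experts; most
  residual error concentrates at the body/tail interface, which the
  failure diagnostics (`failure_diagnostics()`) quantify explicitly.
* `beta'` is, by the cumulative definition, a monotone transform of
  `alpha'` within one case; its discriminative value beyond `alpha'` comes
  from encoding the volume profile, not from independent variation. The
  naive-Bayes independence assumption is therefore knowingly optimistic.
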