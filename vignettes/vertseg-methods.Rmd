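---
title: "Methods: patch-based vertebra localization and instance segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: patch-based vertebra localization and instance segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Segmenting individual vertebrae in CT is hard for two reasons that pull
in opposite directions: semantic segmentation alone fuses neighbouring
vertebrae where processes nearly touch, while detect-then-segment
pipelines need a second network and re-learn vertebra appearance twice.
`vertseg` implements a single-network design that couples both tasks
through a shared encoder:

1. A compact 3D U-Net-style encoder-decoder labels every voxel of a
   32 × 48 × 48 patch as background, vertebra *inner body*, or a
   one-voxel *boundary* shell. The three-label representation is
   produced from instance reference labels by eroding each instance
   with the discrete radius-1 sphere (the 6-connected unit ball): the
   eroded remainder is the body, the eroded-away rim is the boundary.
   Body and boundary partition each instance exactly, so the encoding
   is lossless for the foreground.
2. A regression head consumes the deepest encoder feature map through a
   1 × 1 × 1 convolution and four fully connected layers and emits a
   1 × 12 vector: three offsets (mm, patch center to vertebral body
   center) for the *top*, *mid* and *bottom* vertebra of the patch plus
   three confidence scores. The body center of a vertebra is the center
   of mass of its morphologically opened mask, so thin posterior
   processes do not bias it.

The mid-vertebra is chosen by visibility: a single visible vertebra is
the mid; of two, the lower; of three, the middle; with more than three,
the lowest-confidence vertebra is dropped repeatedly (ties: the topmost
of the tied) until three remain. A vertebra's confidence is the
fraction of its total volume inside the patch — e.g. three consecutive
vertebrae with 15 %, 25 % and 10 % of their volume in the patch receive
confidences 0.15, 0.25, 0.10. An absent neighbour gets confidence 0 and
a mirrored ("plausible") position: the mid-center reflected through the
present neighbour, or a default z-gap when both neighbours are missing.
The 12-vector serialization order is (top offset, mid offset, bottom
offset, conf top, conf mid, conf bottom); the offsets are in
millimetres so the regression target is invariant to voxel-size
choices.

## From patch outputs to instances

At application time the scan is resampled to the
2 × 0.977 × 0.977 mm working grid (axis order (z, y, x), z
cranio-caudal — one convention fixed throughout the package), clipped
to reference percentiles and Z-score normalized with statistics frozen
on a named training set, and cropped to a vertebra VOI anchored on a
pelvis mask, a user-given bottom plane, or the scan bottom. Patches on
a 50 %-overlap lattice (the last patch per axis clamped to the VOI
face, so all inputs are real data rather than zero padding) are pushed
through the network; class probabilities are averaged per voxel and
arg-maxed. Every patch whose predicted foreground reaches at least 15 %
of the typical (mean) vertebra volume casts three votes at
patch-center + offset, weighted by the predicted confidences
(confidences below 0.01 are discarded — near-zero weights destabilize
k-means and such votes carry no information).

The vertebra count is selected by a clustering score built from an
inter-vertebral distance model: for each neighbouring-pair index i
(1 = the lowest pair) a Gaussian \(G^{dst}_i\) is fitted by maximum
likelihood (sample mean, biased SD) to the z-projected center gaps
\(D_i\) of the training scans — 17 pair Gaussians in total — plus one
Gaussian \(G^{diff}\) of the pooled consecutive-gap differences. For a
candidate set of k z-sorted centers,

\[ CS(k) = \min_{i=1..k-2} G^{dst}_i(D_i)\, G^{dst}_{i+1}(D_{i+1})\,
   G^{diff}(D_{i+1}-D_i), \qquad k_{opti} = \arg\max_{k \in [3,19]} CS(k), \]

i.e. the *worst* three-center window decides, which punishes a single
merged or split cluster hard. Weighted k-means (weights = confidences)
supplies the centers for every k; votes inside an exclusion region
(e.g. the segmented pelvis) are removed first.

Instances are then separated: the signed Euclidean distance map of the
body label (negative inside) is computed; each center walks to the
minimum of its 5 × 5 × 5 neighbourhood (iterated to a fixed point, at
most 10 steps); a seeded priority-flood watershed on the distance map
splits the body mask; instance labels grow back over the boundary shell
by constrained one-voxel dilations (contested voxels go to the label
with more face-adjacent claimants, ties to the lower label, at most 5
rounds); unlabeled foreground components are visited largest-first and
adopted as new instances whenever inserting their center of mass does
not decrease CS — capped at 18 instances, the largest count the score
range supports. Finally each instance keeps its largest connected
component, internal cavities are filled by the border-flood inversion
trick, and instances are renumbered bottom to top.

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| working grid | 2 × 0.977 × 0.977 | mm | the median planning-CT grid the method was designed around |
| patch size | 32 × 48 × 48 | voxels | native network input; covers ~2-3 vertebrae |
| overlap | 0.5 | — | every interior voxel seen by 8 patches; integer stride |
| erosion radius | 1 | voxels | one-voxel boundary shell |
| body-center opening | (1, 3, 3) | voxels | removes 2-5-voxel processes; kernel size left open by the method, exposed in the API |
| volume gate | 0.15 | fraction | patches below 15 % of the mean vertebra volume cast no votes (applied inclusively, `>=`) |
| confidence floor | 0.01 | — | votes below it are dropped before clustering |
| k range | [3, 19] | — | score search range; 18 gaps reuse the 17th pair Gaussian for the top-most gap, since only 17 pair models exist |
| sigma floor | 0.5 | mm | keeps degenerate MLE fits from yielding infinite densities |
| localization schedule | lr 1e-4, 400 epochs, MSE | — | the published head schedule |
| segmentation schedule | Adam, lr 1e-2, epochs configurable | — | this package's CPU-scale choice |

Gaussians are evaluated as full normalized densities (the literal MLE
objects); a peak-normalized variant is available behind the
`normalized` flag of `clustering_score()` for sensitivity checks.

## The network at CPU scale

The architecture follows the published design — four tiers, leaky
rectifier activations, instance normalization in the segmentation path,
batch normalization in the head, Kaiming-normal initialization for the
segmentation weights and Kaiming-uniform for the head — but channel
widths are configurable and default small enough to train on one CPU
(the exact widths are not printed in the underlying description, so
16 → 32 → 64 → 128 with a (256, 128, 64, 12) head is this package's
choice, and the tests use 2-tier, 4-channel models). Everything is
implemented inside the package: 3 × 3 × 3 convolution as an im2col
gather plus a BLAS matrix multiply (compiled), hand-written backward
passes verified against numerical differentiation in the test suite,
and Adam optimization. The soft Dice loss is 3-class macro-averaged
with smoothing 1e-5. The segmentation branch is fully convolutional, so
training may use smaller sub-patches (the tests use 16 × 24 × 24) while
inference stitches at the native patch size; the head requires the
native bottleneck shape. Augmentation (per-axis rotation ±15°,
isotropic scaling ±25 %) warps patch, labels and offset vectors
together so the regression target stays geometrically consistent; it is
off by default in the CPU-scale training runs.

During localization training the encoder is frozen and bottleneck
tensors are precomputed, so only the head is optimized — matching the
two-stage schedule of the underlying method.

## What the phantom generator emulates — and what it does not

`generate_spine_phantom()` builds a bottom-to-top stack of 3-18
vertebra-like objects: an axis-aligned ellipsoidal body (default
semi-axes 11 × 14 × 16 mm) with a thin posterior box process
(3 voxels wide in x, 20 mm long), inter-center z-gaps drawn from a
Gaussian (default 30 ± 2 mm, matching lumbar spacing statistics),
two-level CT-like intensities (soft tissue 40, bone 400) with additive
Gaussian noise (SD 20), and optional collapsed vertebrae (z-extent
flattened to 45 % of nominal) or fused pairs (a bony bridge making the
pair 26-connected). Gaps are clipped away from geometric overlap so
non-fused neighbours stay disjoint. The same spec and seed give
bit-identical phantoms.

The phantom deliberately omits cortical/trabecular texture, anatomical
shape variation, curvature of the spine, partial-volume effects, metal
artifacts and the pelvis. Tests passing on phantoms therefore validate
the *geometric and model-based machinery* — three-label round trips,
vote clustering, count selection, watershed separation, recovery — and
the *trainability* of the network on a simple intensity task; they do
not certify segmentation accuracy on clinical CT, which requires real
scans and full-scale training outside this package's scope.

## Numerical choices and degenerate inputs

* Morphology operates in voxel space (radii quoted in voxels); centers
  and distances are reported in millimetres using the anisotropic
  spacing.
* Percentiles use linear interpolation between order statistics; the
  normalization SD is floored at 1e-6.
* Watershed flooding uses 26-connectivity with ties broken by insertion
  (scan) order; mask voxels unreachable from any seed are assigned to
  the nearest seed. Seeds that land off the body mask after refinement
  are snapped to the nearest body voxel.
* Connected components use 26-connectivity (diagonal leakage bridges
  must stay in one component).
* k-means uses weighted probabilistic farthest-point seeding under a
  fixed seed; an emptied cluster is re-seeded at the vote with the
  largest weighted squared distance to its current center, each such
  vote used at most once per iteration. z-sorting ties break by
  (z, y, x).
* Candidate k values exceeding the number of distinct votes score
  `-Inf` rather than erroring inside the search.
* A patch with no instance voxels is *not* a localization target;
  constructors raise an error and callers filter.
* The recovery step treats a component's center as its plain center of
  mass (a fragment need not contain a clean body to open); components
  under 10 voxels are ignored as noise.

## Design decisions taken where the method left options open

* **Offsets in millimetres** (not voxels) — spacing-invariant targets.
* **Clamped border patches** instead of zero padding — all network
  inputs are real data.
* **Mirror extrapolation** for absent neighbours, default-gap fallback.
* **12-vector component order** fixed as documented above.
* **Trilinear intensity / nearest-neighbour label resampling** with
  physical extent preserved to within one voxel.
* **Surface distances directed from the predicted surface** (signed by
  containment in the reference), Hausdorff symmetric; surface voxels
  use face connectivity.
* The pelvis prerequisite is *not* re-implemented: the pipeline accepts
  a pelvis mask or a bottom plane, mirroring the two evaluation
  categories of the underlying study design.

## Validation experiments in the test suite

The acceptance tests run scaled-down but complete experiments chosen to
fit comfortably in CPU minutes; the sizes are the package's own choices:
count selection uses 50 vote clouds over k ∈ 3..10 at model spacing
with vote noise at 15 % of the mean gap; post-processing exactness and
recovery each use 10 phantoms (3-8 vertebrae); the training smoke test
fits a 2-tier, 4-channel model on 160 sub-patches from 20 four-vertebra
phantoms and evaluates stitched foreground Dice on 5 held-out phantoms.
In the recovery experiment the deleted instance is drawn from the
interior of the stack — the collapsed/missed-vertebra scenario the
algorithm targets; for an end-of-stack deletion the acceptance rule
CS(k+1) ≥ CS(k) can at best tie, because the added window can only
lower the minimum, so recovery of terminal vertebrae is inherently
score-neutral and not a sharp test.

## Known limitations

* The CNN here validates the architecture and training loops at CPU
  scale; reproducing clinical-grade accuracy requires GPU-scale
  training on real CT, outside this package's scope.
* Fused vertebrae from extreme low bone density are split only if the
  watershed finds a neck between the seeds; the failure mode is
  acknowledged, not solved.
* Anatomical naming (L5 vs L4 ...) is intentionally out of scope; the
  output numbering is purely bottom-to-top.
* Metal artifacts and scanner-specific HU calibration are not handled.
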