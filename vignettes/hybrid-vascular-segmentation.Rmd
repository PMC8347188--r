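---
title: "Hybrid expert-system / convolutional segmentation of the abdominal vascular tree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid expert-system / convolutional segmentation of the abdominal vascular tree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselseg)
```

## The problem

Contrast-enhanced CT angiography (CTA) of the abdomen shows the arterial
lumen as a bright tube (contrast-filled blood, roughly 250–350 HU), the
intraluminal thrombus lining an aneurysm as a faint soft-tissue crescent
(~50 HU against ~40 HU background), and the spine as a very bright
posterior column (cortical bone ≳ 700 HU) that any automatic vessel
detector must discriminate against.  `vesselseg` implements a fully
automatic segmentation of these three structures by combining two
complementary engines:

* a **rule-based expert system** — HU windowing, boundary propagation and
  morphological active contours — which is precise where its assumptions
  hold (good contrast, thin slices) but brittle on degraded acquisitions;
* **convolutional encoder–decoder networks** trained *on the expert
  system's own output masks*, which localise structures robustly even on
  low-contrast, thick-slice, noisy scans.

The hybrid workflow uses the networks for localisation (spine erasure,
lumen seeding, thrombus proposal) and the expert machinery for precision
(contour refinement, component filtering, elliptic smoothing).  The point
of the construction is that no manual annotation enters the training
loop: the expert system generates the labels, and the hybrid then
outperforms its own teacher on degraded data.

## The expert system

All rules live in `expert_config()`; every run can snapshot the full
configuration to YAML.  The defaults, with units:

| parameter | default | meaning |
|---|---|---|
| `smoothing_sigma` | 0.5 mm | isotropic Gaussian pre-smoothing (per-axis sigma = mm / spacing) |
| `bone_threshold` | 200 HU | spine candidate threshold |
| `lumen_window` | 150–600 HU | contrast-filled lumen candidates |
| `seed_eccentricity_max` | 0.95 | roundness bound on the seed region |
| `acwe_iterations` | 40 | morphological active-contour steps |
| `propagation_overlap_min` | 0.5 | Dice acceptance for slice-to-slice propagation |
| `spine_closing_mm` | 5 mm | z-closing that bridges inter-vertebral gaps |
| `thrombus_dilation_mm` | 6 mm | snake initialisation ring around the lumen |
| `thrombus_window` | −20–80 HU | soft-tissue clamp before the thrombus snake |
| `thrombus_min_contrast` | 6 HU | detection gate over local background |

**Spine.**  Thresholding at 200 HU, then a morphological closing whose
structuring element is tall along z (radius `spine_closing_mm`) but only
one voxel in-plane.  The anisotropy is deliberate: the inter-vertebral
gaps run along z, while an isotropic ball of the same radius would fuse
the vertebral column with a neighbouring aneurysm.  3D connected
components (26-connectivity) whose centroid lies in the anterior half are
discarded — this is what rejects the equally-bright contrast-filled
lumen.  If nothing exceeds the threshold the result is an empty mask with
a warning, not an error: an absent spine is a documented failure mode
downstream consumers must survive.

**Lumen.**  A seed is searched in the mid-volume slice (scanning outward
if that slice has none): the largest connected region inside the HU
window, anterior to the spine centroid, with moment eccentricity below
0.95; ties break toward the spine's midline column, because the aorta is
prevertebral and near-midline.  The seed is refined by a morphological
active contour without edges (ACWE) and propagated slice by slice in both
directions, each converged contour initialising its neighbour; a slice is
accepted while the Dice overlap between initialisation and converged
region stays ≥ 0.5.  When no admissible seed exists anywhere the result
carries `status = "lumen-not-found"` — the same accounting the hybrid
uses to decide it must supply a network seed.

**Morphological ACWE.**  The contour is a binary level set evolved by
connected morphological operators only: each step recomputes the two
region means, flips only contour-adjacent pixels toward the nearer mean
(so the region moves at most one pixel per step and cannot jump onto
disconnected bright anatomy), and applies the sup-inf/inf-sup curvature
smoothing over four 3-pixel line segments.  There is no PDE time step, no
CFL condition and no re-initialisation, which is why it is preferred
here: fewer parameters and no numerical instability.  Evolution is
restricted to a bounding box around the initialisation, and a step that
leaves the level set unchanged terminates the loop early.

**Thrombus.**  The snake is initialised from the lumen dilated by
`thrombus_dilation_mm` and runs on the soft-tissue-windowed,
additionally smoothed slice (`thrombus_smooth_mm`; the thrombus contrast
is an order of magnitude fainter than the lumen's).  Three refinements
were necessary to make a Chan–Vese-type snake work at 10 HU contrast:

1. *Robust intensity anchors.*  Background is estimated as the median
   beyond the search annulus; the thrombus level as the 0.85 quantile of
   the annulus.  If they differ by less than `thrombus_min_contrast`
   there is nothing to find and the slice is skipped — otherwise the
   snake degenerates into accreting positive noise blobs.
2. *Halo neutralisation.*  The partial-volume halo around the clamped
   lumen is set to the background estimate before evolution; left in
   place, its bright values either drag the inside mean upward until the
   true thrombus is shed, or let the contour creep around the lumen on
   partial-volume brightness.  After convergence the neutralised band is
   re-filled radially where a crescent was detected.
3. *Component gating.*  Detected components must be sizeable
   (`thrombus_min_area_mm2`), lumen-adjacent, and clearly brighter than
   background.

Thin crescents at the axial ends of an aneurysm fall below these gates;
the expert system truncates there.  That truncation is a known behaviour
of rule-based snakes and is precisely what the network half of the hybrid
recovers.

## The networks

`build_unet()` constructs a symmetric encoder–decoder: per level two 3×3
convolutions, 2×2 max-pooling down, nearest-neighbour resize plus
2×2 convolution up with skip concatenation, a penultimate 3×3 convolution
to 2 channels and a 1×1 head (sigmoid for one output channel, softmax
over 3 channels for the background/lumen/spine variant).  There is no
batch normalisation.  Hidden activations are leaky rectifiers (slope
0.01): the 2-channel penultimate bottleneck is prone to dying under a
hard rectifier with the soft-Dice loss — a dead bottleneck makes the
whole output constant — and the leak guarantees gradient flow at every
seed; the activation has no parameters, so the counts below are
unaffected.  At depth 5 and base width 64 the trainable-
parameter counts are exactly 31,031,685 (binary) and 31,031,691
(multi-class); the counts are reproduced independently by the per-layer
closed form Σ filters·(kernel_area·in_channels + 1) and asserted in the
test suite.  Under the counting used here — the two 3×3 trunk
convolutions per level, excluding the upsampling convolutions, the
2-channel fusion and the head — the depth-5 network has 18 hidden layers,
which `count_hidden_layers()` verifies by introspection.

The network stack (forward, backward, Adam, augmentation) is implemented
natively in this package on an im2col + GEMM kernel (RcppArmadillo); a
finite-difference gradient check is part of the test suite.  Inputs are
standardised per slice (zero mean, unit variance), which is also what
lets a network trained on well-enhanced scans respond on low-contrast
ones.

**Training** (`train_unet()`): Adam minimising the soft-Dice loss
`1 − (2Σpt + ε)/(Σp + Σt + ε)`, ε = 10⁻⁶; random augmentation of each
training slice (rotation ±10°, shifts ±5 %, zoom ±10 %, horizontal flip);
monitoring of the hard Dice on a 10 % held-out split; termination at
`max_epochs` or when the monitored Dice changes by less than 10⁻³ for 3
consecutive epochs (`stagnation_stop()`).  Everything — shuffling,
augmentation, initialisation — is reproducible under the configuration
seed.  A learning rate of 10⁻⁵, suited to full-scale training corpora,
is the default;
desk-scale experiments in this package's tests use 10⁻³ so that the small
networks converge within a handful of epochs.

Two binary networks (spine, lumen) are preferred over one multi-class
network: under equal training budgets the binary pair's mean Dice
matches or exceeds the multi-class model's, which the test suite checks
over three seeds at reduced scale.

## The hybrid workflow

`segment_lumen_hybrid()` runs the spine and lumen networks per slice,
thresholds the probability maps at 0.5 (a pixel at exactly 0.5 is
foreground), sets the predicted spine pixels to 0 HU — the erasure value
is kept at 0 deliberately, matching the workflow this package
re-implements, even though 0 HU is water-like — and re-runs the expert
lumen segmentation on the filtered volume with the network's lumen mask
replacing the brightness-based seed search (the seed slice is the slice
with the largest predicted component; seed-only use, the network mask is
not intersected with the result).  Provenance records which seed source
was used.  If the network predicts no lumen at all, the expert seed
search is the fallback.  Network predictions also pass an anatomical
plausibility gate before they are allowed to act: a predicted spine,
lumen or thrombus covering more than a quarter of the volume is a
degenerate network output, not anatomy (the vertebral column and the
aorta each occupy a few percent of an abdominal scan), and is ignored —
spine erasure is skipped, the lumen seed falls back to the expert
search.  The gate is what keeps a badly trained network from erasing the
whole volume instead of just the spine.

`segment_thrombus_hybrid()` thresholds the thrombus network's maps and
cleans them with `postprocess_thrombus()`: 26-connected components whose
1-voxel dilation does not intersect the lumen are removed (a crescent
touches but does not overlap the lumen — hence the dilation), and each
axial section of the survivor is smoothed by a moment-matched ellipse fit
of the combined thrombus ∪ lumen region.  The fitted ellipse is iterated
through fit-and-rasterise until the rasterisation is a fixed point and
its parameters are quantised to 1/8 pixel, which makes the smoothing
exactly idempotent; the ellipse replaces the section only when its Dice
against the unsmoothed region reaches `ellipse_floor` (default 0.6), so
genuinely non-elliptic sections pass through untouched.

## The phantom generator

`generate_phantom()` rasterises a parametric abdomen: a soft-tissue
background (40 ± 15 HU), a contrast-filled lumen tube (300 ± 30 HU) with
an optional aneurysmal bulge, a crescent thrombus (50 ± 15 HU) built as a
posterior-shifted outer ellipse minus the lumen (so it lines the bulge
and touches the lumen wall, matching the elliptic cross-sections the
smoothing step assumes), and a posterior bone column (700 ± 100 HU) with
periodic inter-vertebral gaps that make naive 3D connectivity fail.
`noise_sd` is the additive Gaussian noise SD of the background class;
other classes scale proportionally to their catalogued SD, so
`noise_sd = 0` yields exact class means (useful for analytic tests) and
the default 15 reproduces the listed per-class SDs.  `contrast_scale`
multiplies the lumen-minus-background difference; `mode = "ami"` sets
contrast 0.5, slice thickness 2.5 mm and doubled noise — the degraded
regime.  `generate_dataset()` jitters spec fields over ranges with
per-volume seeds derived from one master seed and can emit NIfTI plus a
tab-delimited manifest.

What the phantoms deliberately do **not** emulate: organ texture, the
iliac bifurcation, stent-graft metal artefacts, beam hardening, and
patient-to-patient anatomic variability beyond the jittered geometry.
Passing the phantom suites therefore demonstrates the pipeline's
mechanics and its degradation behaviour, not clinical performance.

## Evaluation machinery

`metrics_report()` computes voxel confusion counts and Dice, Jaccard,
sensitivity, specificity, volume similarity
(`1 − |FN−FP|/(2TP+FP+FN)`, equivalently `1 − |V₁−V₂|/(V₁+V₂)`) and the
Hausdorff distance (exact, on boundary voxels, Euclidean; voxel units by
default, millimetres on request — reported tables of this kind rarely
state which, so both are provided).  Conventions for degenerate cases are
explicit and flagged rather than dropped: two empty masks have Dice 1, an
empty prediction against a non-empty truth scores 0, and an empty mask
makes the Hausdorff distance undefined.  `compare_methods()` pairs two
per-slice metric tables and reports mean ± SD, min–max and the two-tailed
paired Student's t-test per metric (`stats::t.test`); zero-variance
differences are flagged degenerate, with p = 1 when the two methods agree
exactly.

## Desk-scale profile and problem sizes

All shipped tests run on 128 × 128 × 10–16 phantoms (full 512 × 512
volumes use the same code paths).  The training-on-synthetic-labels
experiment in the test suite uses 5 expert-labelled clean phantoms
(80 slices; thrombus slices screened for a sizeable expert detection,
mirroring the quality screening such corpora receive), depth-4 networks
at base width 8, learning rate 10⁻³, and 5 / 6 / 12 epoch caps for the
lumen / spine / thrombus networks, evaluated on 10 degraded phantoms over
3 training seeds.  These sizes are the package's reproducibility profile:
large enough for the hybrid-gain direction to be stable, small enough to
run on a laptop CPU.

## Known limitations

* The expert thrombus snake truncates thin crescents (by design of its
  gates); only the hybrid path recovers them.
* The hybrid's spine erasure uses the literal 0 HU convention.
* Multi-frame/enhanced DICOM, non-axial acquisitions and DICOM-SEG are
  out of scope; the DICOM reader is a validating subset (explicit-VR
  little-endian, single-frame CT) that refuses rather than guesses.
* 3D (volumetric) network variants are not implemented; the slice-wise
  2D design with slice-to-slice propagation is intentional.
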