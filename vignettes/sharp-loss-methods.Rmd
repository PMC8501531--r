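---
title: "Sharp loss for dose-imbalanced radiotherapy dose prediction: models and methods"
author: "sharpdose authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sharp loss for dose-imbalanced radiotherapy dose prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sharpdose)
```

## The problem: dose imbalance

Voxelwise dose prediction learns a map from a labelled anatomy (planning
target volume, organs at risk, other tissue, air) to the 3D dose
distribution a planner would produce. In thoracic sites the imaged volume
is dominated by voxels that carry almost no clinical information: roughly
three quarters of all voxels lie outside the body at exactly zero dose,
and of the in-body voxels roughly three quarters again receive less than
500 cGy. A network trained with the plain mean-squared-error (MSE)
objective

$$\mathrm{MSE} = \frac{1}{n} \sum_{i=1}^n (\hat D_i - D_i)^2$$

spends most of its gradient budget on those voxels, predicts them almost
perfectly, and under-fits the steep, clinically critical dose around the
target.

## The sharp loss

`sharpdose` implements a sigmoid-modulated MSE, the *sharp loss*:

$$\mathrm{SL} = \frac{1}{n} \sum_{i=1}^n
  \frac{1}{1 + e^{-(D_i - s)\,\gamma}} \, (\hat D_i - D_i)^2 ,$$

where doses are on the normalized scale ($1.0 \equiv 6000$ cGy), $s = 0.03$
shifts the sigmoid along the dose axis so that zero-dose voxels sit on its
suppressed shoulder, and $\gamma \ge 0$ controls how hard low-dose voxels
are down-weighted. The weight depends only on the *ground-truth* dose, so
it rescales the error signal without distorting its direction.

Three analytic quantities characterize the loss ([`lossConfig()`],
[`modulatingFactor()`], [`demarcationDose()`]):

* the modulating factor is strictly increasing in dose, bounded in (0, 1),
  and equals $1/2$ exactly at the shift (180 cGy);
* at zero dose and $\gamma = 100$ the factor is
  `r round(modulatingFactor(0, lossConfig(gamma = 100)), 3)`: a zero-dose
  voxel contributes about 4.7% of what it would contribute to the MSE;
* the *demarcation dose* $D_0$, the ground-truth dose at which the sharp
  loss reaches 99% of the MSE loss, has the closed form
  $D_0 = 6000\,(s + \ln(0.99/0.01)/\gamma)$ cGy;
  at $\gamma = 100$, $D_0 =$
  `r round(demarcationDose(lossConfig(gamma = 100)), 2)` cGy. Above $D_0$
  the two losses are practically identical; below it the sharp loss decays
  smoothly to its floor.

$\gamma$ trades off the two error regimes: small $\gamma$ pushes $D_0$ up
and leaves low-dose precision intact, large $\gamma$ sharpens the step and
eventually sacrifices accuracy in the 0–455 cGy range. $\gamma = 100$ is
the recommended operating point; the comparison harness scans
$\gamma \in \{1, 25, 50, 100, 250, 500\}$.

Two deliberate design choices: predictions are *never clamped* inside the
loss (the network head is linear and clamping would silently zero
gradients), and $\gamma = 0$ is accepted by the loss (it degenerates to
half the MSE) but rejected by `demarcationDose()`, where no finite
demarcation point exists. The sigmoid is evaluated with a sign-branching
form so large $\gamma$ cannot overflow, and its output is clamped into
the open unit interval (to within a few ulps of the endpoints): without
the clamp the weight
saturates to exactly 1.0 for arguments above about 37, which would
collapse the mathematically strict bounds $0 < w < 1$ and
$\mathrm{SL} < \mathrm{MSE}$ at double precision. Strict monotonicity in
dose holds on the unsaturated part of the axis and is tested there.

## The synthetic phantom

The clinical datasets such a model is trained on (here: left-breast
plans delivered with tangential arcs) are not redistributable, so the
package ships a parametric left-thorax phantom ([`generateAnatomy()`],
[`generateDose()`]) whose purpose is purely statistical: to reproduce the
*imbalance structure* that motivates the loss, not to be dosimetrically
accurate.

* **Anatomy.** An elliptical body cylinder whose in-plane semi-axes are
  solved in closed form from the target outside-body fraction (default
  0.7452); two lung ellipsoids; a heart ellipsoid left of the midline; a
  posterior spinal-cord cylinder; and a half-ellipsoid PTV clipped to soft
  tissue on the left anterior chest wall. Organ sizes and positions are
  jittered per seed (±5% by default). Labels are mutually exclusive and
  the PTV always lies strictly inside the axial extent.
* **Dose.** Two opposed beams whose common axis runs tangent to the left
  chest through the PTV centroid. Each beam contributes
  $\exp(-\mu\,d_{\mathrm{entry}})$ depth attenuation ($\mu = 0.005$/mm, an
  effective 6-MV falloff) inside a field shaped by Gaussian-smoothed edges
  ($\sigma = 6$ mm penumbra, 5 mm margin around the PTV projection). The
  sum is modulated by a smooth 3% heterogeneity field, lightly smoothed,
  forced to zero outside the body, scaled so the PTV D95 equals the
  5000 cGy prescription, and capped at 1.2 times the prescription.
* **Calibration.** The outside-body fraction is exact by construction up
  to jitter; the field margin was fixed once so that the default geometry
  yields an in-body below-500 cGy fraction near the 0.7730 target. Both
  statistics are verified by census over seeds in the test suite
  (outside in [0.70, 0.80], low-dose in [0.69, 0.85]).

What the phantom does *not* emulate: tissue heterogeneity corrections,
scatter, arc delivery (the "tangential beams" are static parallel fields),
inter-planner variability, and anatomical detail beyond five organs.
Passing tests therefore demonstrate that the loss behaves as designed
under realistic imbalance — not that the model reaches clinical accuracy
on real plans.

D95 is defined as the 5th percentile of the PTV voxel doses
(linear-interpolated, the R type-7 quantile); the same interpolation rule
is used for every $D_x$ metric, including $D_1$/$D_{99}$ in the
homogeneity index.

## The network

[`buildUNet()`] constructs an encoder–decoder regression network: `depth`
(default 5) down levels of two 3×3×3 convolution modules — each
convolution followed by a ReLU and a batch normalization — with 2×2×2 max
pooling between levels; the deepest level acts as the bottleneck and does
not pool, so the `depth - 1` decoder levels (transposed-convolution
upsampling, skip concatenation, two more convolution modules) restore the
input grid exactly; a final 1×1×1 convolution with linear activation emits
the dose. In 2D mode kernels are 1×3×3 and pooling 1×2×2, so axial slices
pass through the identical code path independently.

Design points that the architecture description leaves open, and how they
are resolved here:

* **Padding.** Only same-padding is offered. A valid-padded network cannot
  return the input grid, which the task's I/O contract requires;
  `paddingMode = "valid"` is rejected with an explanatory error rather
  than silently reinterpreted.
* **Encoder/decoder symmetry.** Five pooled levels cannot be undone by
  four upsampling levels; the deepest level therefore omits its pool. This
  is the conventional bottleneck reading and makes the network exactly
  shape-preserving.
* **Channel schedule.** Widths are unspecified in the recipe; the default
  is 16 doubling per level, configurable. The package's tests run much
  smaller instances (base 2–4, depth 2–3).
* **Upsampling.** Transposed convolution by default;
  nearest-neighbour-plus-convolution is selectable.
* **Batch-norm order.** The literal conv → ReLU → BN reading is the
  default; conv → BN → ReLU is available via `bnOrder = "bn_relu"`.
* **Output head.** Zero-initialized, so an untrained model predicts
  exactly zero dose — a convenient, verifiable anchor for tests, and a
  neutral starting point given that most target voxels are zero.

The implementation is pure R over BLAS matrix primitives (im2col
convolution, explicit backpropagation, Adam); parameter counts of built
models are checked against a closed form ([`unetParameterCount()`]).
Training uses Adam (learning rate 0.001, batch 2), and a
reduce-on-plateau schedule: when the monitored validation loss has not
strictly improved for 5 epochs the rate is multiplied by 0.1, never below
1e-7 ([`plateauSchedule()`], [`updatePlateau()`]). "5 iterations" is read
as 5 validation epochs — the standard plateau-scheduler semantics; a
per-step patience of 5 would fire immediately. By default the scheduler
monitors the loss being trained; `monitorMse = TRUE` switches the monitor
to plain MSE so that schedules are comparable across loss variants.

## The comparison experiment

[`compareLosses()`] reproduces the experimental design around the loss:
one model per variant (MSE baseline plus each $\gamma$), all trained with
identical initialization seeds, identical train/validation/test splits and
identical schedules, so the loss is the only difference. Held-out test
cases are evaluated with the full suite: MAD by ground-truth dose band
(half-open intervals 0–500 through >5000 cGy partitioning the in-body
region), MAD per organ, the standard deviation of the signed in-body
error, DVH metrics (PTV D95, HI, CI; heart and lung mean doses and
V5/V20/V30), and a paired Wilcoxon signed-rank test of each sharp variant
against the MSE baseline per organ.

Banding is always on the *ground-truth* dose: the question the banded
report answers is "how well is the region that truly receives X predicted",
which predicted-dose banding would circularly distort.

The Wilcoxon test is implemented in-package because the required policy —
zeros dropped, ties mid-ranked, an exact enumeration null for $n \le 15$
even under ties, normal approximation with continuity and tie correction
above — is not available as a single stock call; the stock implementation
serves as an independent cross-check in the tests.

## Problem sizes and numerical choices

The package's own experiments are desk-scale by design: phantoms default
to a 32 × 96 × 96 grid (5 mm slices, 500 mm in-plane field of view) with a
64 × 256 × 256 full-scale preset; the training tests use 16 × 32 × 32 and
8 × 16 × 16 grids, models of depth 2–3 with 2–4 base channels, and about
10 epochs. The directional claim — that the sharp loss at $\gamma = 100$
yields lower PTV-region MAD and lower in-body error standard deviation
than the MSE loss — is checked as a majority vote over 5 seeded repeats of
a 12-case experiment at that scale. These sizes establish the *direction*
of the effect under controlled imbalance; they make no claim about effect
magnitudes at clinical scale.

Other numerical conventions: all loss math happens on the normalized
[0, 1] dose scale, and cGy appear only at I/O and reporting boundaries;
band partition conservation (voxel-weighted recombination of band MADs
equals the region MAD) is tested to 1e-9; the demarcation closed form is
tested against numeric root-finding to 1e-6 on the normalized scale;
analytic loss gradients are tested against central finite differences to
1e-5 relative; empty masks, empty bands and all-zero Wilcoxon differences
are reported as flagged undefined values, never silent zeros.

## Known limitations

* The phantom's beam model is analytic; absolute dosimetric quantities
  (e.g. OAR dose levels) are plausible but not clinically meaningful.
* Pure-R training is practical at desk scale only; the full
  64 × 256 × 256, depth-5, 16-channel configuration is constructible and
  shape-checked but not intended for CPU training.
* The evaluation suite deliberately implements a single paired test with
  no multiplicity correction, mirroring standard practice for this
  experiment type.
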