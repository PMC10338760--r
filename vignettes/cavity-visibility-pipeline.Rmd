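---
title: "Resection-cavity visibility, cohort pre-selection and CTV expansion: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resection-cavity visibility, cohort pre-selection and CTV expansion: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cavityqa)
```

## The problem

After resection of a pediatric posterior-fossa medulloblastoma, the boost
target for radiotherapy is the resection cavity (treated as the GTV) plus a
margin (the CTV). On CT — often the only modality available in
resource-constrained centers — the cavity's visibility varies enormously:
blood products, edema and collapse can leave a cavity nearly isodense with
the surrounding brain. A segmentation model trained or evaluated on such
invisible cavities learns little and scores badly for reasons that have
nothing to do with the model. `cavityqa` implements the quantitative
machinery for dealing with this: scoring cavity visibility, filtering a
cohort on visibility, continuity and location, expanding GTVs to
anatomically constrained CTVs, and evaluating predicted contours against
references in a 2×2 design (two training cohorts × two test cohorts).

## Visibility metrics

For a GTV mask on a CT volume, the package crops a 3D window: the GTV
bounding box expanded by `px_xy` voxels per side in-plane and `px_z`
slices per side along z (defaults 10 and 2). Within the window,

$$\mathrm{Contrast} = \bar{x}_{ROI} - \bar{x}_{bkg}, \qquad
  \mathrm{CNR} = \frac{\bar{x}_{ROI} - \bar{x}_{bkg}}{\sigma_{bkg}},$$

where $\bar{x}_{ROI}$ is the mean HU inside the GTV, and
$\bar{x}_{bkg}$, $\sigma_{bkg}$ are the mean and sample standard deviation
of the window voxels outside the GTV. Voxels with HU ≥ 1000 (bone) are
omitted from both statistics, so a bone/tissue interface cannot masquerade
as a visible cavity edge.

Decisions taken where the procedure was genuinely open:

* **Expansion per side.** The crop amounts are applied per side of the
  bounding box (a 10-voxel expansion widens the box by 20 voxels). Both
  amounts are arguments, so per-total readings can be reproduced by
  halving them.
* **Bone exclusion applies to ROI and background alike.** Restricting it
  to the background would leave the ROI mean undefined when a cavity
  touches calcified material; applying it uniformly keeps the metric
  total.
* **Sample SD (n−1)** in the CNR denominator, the standard estimator.
* **Volumetric, not slice-wise**: one 3D window, one contrast, one CNR
  per case.
* **Air is not excluded.** Only the bone rule is applied; low-HU
  structures (sinus air) entering an unusually large window would bias the
  background mean downward. The phantom geometry keeps windows inside
  brain-or-bone for this reason (below).

The low-visibility filter excludes a case when the selected metric lies
inside a closed band — contrast in [−10, 10] HU or CNR in [−0.5, 0.1] by
default. Band endpoints count as inside (excluded): the conservative
reading when the boundary behavior is unspecified. Manual 1–4 visibility
scores are accepted as annotations (`visibility_score()`,
`score_summary_table()`); the package never infers them from images.

## Cohort pre-selection

Three criteria, applied in the fixed order continuity → location →
visibility:

* **Continuity**: the GTV must form a single 26-connected component.
  26-connectivity is the most permissive standard 3D connectivity, so
  regions touching only at a corner still count as continuous.
* **Location**: at least 95% of the GTV volume must lie inside the
  posterior-fossa mask. The fraction threshold (`min_fraction`, default
  0.95) turns a visual criterion into an automatic, testable one.
* **Visibility**: the band filter above.

Each removed case is attributed to the *first* criterion it fails, so the
removal counts read like a sequential curation narrative; the surviving
set itself is order-independent (verified by a property test).

`split_cohort()` shuffles under a seed and rounds `train_fraction × n`
half away from zero. `build_experiment_arms()` crosses the two model
bindings (full vs. pre-selected training) with the two test sets, where
the pre-selected test set is the intersection of the pre-selected cohort
with the full test partition — guaranteeing no arm tests on its own
training cases (asserted at construction).

## CTV expansion

The clinical rule is a 1.5 cm anatomic expansion of the GTV confined to
the brain and excluding the brainstem, with the margin reduced to 0.5 cm
toward the brainstem when the GTV is immediately adjacent to it.
`expand_gtv_to_ctv()` realizes "anatomic expansion" as Euclidean
distance-transform thresholding in millimetres (exact separable transform
honouring anisotropic spacing), not voxel dilation — margins are stated in
cm while grids are anisotropic.

The directional reduction has no canonical geometric construction, so the
package declares one: when the GTV is within `adjacency_mm` (default 2 mm,
about one slice) of the brainstem, the allowed margin varies spatially as

$$m(v) = m_{red} + (m_{nom} - m_{red})\cdot
  \min\!\left(1, \frac{d_{bs}(v)}{m_{nom}}\right),$$

i.e. 5 mm at the brainstem surface, recovering linearly to the full 15 mm
at and beyond 15 mm from the brainstem. Both endpoints match the stated
margins; the linear ramp is the simplest deterministic interpolation and
is asserted voxel-for-voxel in tests. If excluding the brainstem would
remove GTV voxels, they are excluded and a warning reports the overlap
volume — the "if possible" escape clause is surfaced, not silently
resolved.

## Contour metrics

DSC, precision and recall are voxel-count ratios; DSC is identically the
harmonic mean of precision and recall (property-tested). Surface distances
use surface voxels (mask voxels with a face-adjacent outside neighbor;
the volume boundary counts as outside) and voxel-center-to-voxel-center
distances in mm, so results are bit-reproducible without sub-voxel
meshing. HD is the exact maximum over both directed distances (not HD95);
MSD is the mean of the two directed means. Comparing two empty masks is an
error rather than DSC = 1 — silent perfection on empty predictions would
hide segmenter failure; an empty prediction against a non-empty reference
is recorded as DSC 0 with undefined surface distances. The model
comparison uses the classical pooled-variance two-sample t-test on
per-case DSC (Welch behind a flag); the other metrics are reported
descriptively.

## The phantom generator

`generate_phantom()` builds the statistical situation the visibility
analysis assumes, with known truth:

* an ellipsoidal brain whose voxels are iid Normal(35, σ²) HU (35 HU is
  the level of the standard brain display window);
* a resection cavity of one or more balls whose voxels are Normal(35 + Δ,
  σ²) — Δ is the *programmed contrast*, recoverable by the visibility
  module (bias ≪ σ, verified over seeded replicates);
* a thick constant-HU skull shell (1200 HU) around the brain. The shell is
  deliberately thick so that crop windows overshooting the brain land in
  bone — which the HU ≥ 1000 exclusion removes — rather than in air, which
  nothing removes (the air gap noted above). Air (−1000 HU) fills the
  volume corners;
* a posterior fossa modeled as the inferior-posterior sector of the brain
  ellipsoid, and a cylindrical brainstem anterior-inferior to it. Only
  containment logic is exercised; no anatomical fidelity is claimed;
* hard cavity edges by default; `edge_blur_mm` applies a Gaussian edge
  profile for robustness experiments where partial-volume-like gradients
  matter.

Defaults: 128×128×64 voxels at 1×1×2.5 mm (2.5 mm is a typical pediatric
head-CT slice thickness; in-plane 1 mm is a documented convention since
clinical in-plane pixel sizes vary), cavity radius 10 mm, seed-determined
noise. A fixed seed reproduces a phantom, and a cohort, bit-identically.

What the phantom does *not* model — and therefore what passing tests do
not show about clinical data: CT reconstruction texture and correlated
noise, beam hardening, partial-volume averaging at 2.5 mm slices, real
anatomy (sulci, ventricles, sinus air near the fossa), age-dependent
morphology, and human inter-observer contouring variability. The contrast
and CNR statistics depend only on means and a standard deviation, which
iid Gaussian noise controls exactly; that is the regime the generator
emulates.

## The segmenter slot

The study design places a trained 3D segmentation network in the model
slot. `cavityqa` abstracts that slot as a contract —
`fit(training_cases)` returning a `predict(case)` function — and ships a
deterministic threshold-plus-morphology baseline
(`baseline_segmenter()`): HU band inside a search region, 1-voxel
closing, largest 26-connected component above a volume floor. The
baseline has no trainable parameters (its `fit` ignores the training
cases), which is exactly what makes the 2×2 design's *structural*
findings testable: a segmenter that cannot see zero-contrast cavities
fails on them in whichever test set they appear, so pre-selecting the
test set must raise the mean DSC. Its HU band must be supplied by the
user; it is a test vehicle, not a clinical claim.

## Numerical conventions

* Voxel indices are 1-based (R convention); the physical position of voxel
  $(i,j,k)$ is its center, $origin + (i-1,j-1,k-1)\cdot spacing$, in mm.
  All distances are computed in mm from the header spacing, never in
  voxel counts.
* Masks are written as unsigned 8-bit NIfTI (0/1); any nonzero value
  reads as true. NIfTI stores spacing/origin as 32-bit floats; voxel data
  round-trip exactly, grid geometry to float precision.
* The distance transform is the exact separable
  Felzenszwalb–Huttenlocher algorithm with per-axis spacing weights,
  verified against an all-pairs oracle.
* `split_cohort()` rounds half away from zero; an 80% split of 104 cases
  gives 83/21 (documented as the rule's output, not a clinical
  conformance target).
* Degenerate inputs fail loudly: empty GTVs, all-bone ROIs, fewer than
  two background voxels, zero background SD in CNR mode (configurable to
  a flagged NA), both-empty mask comparisons, and pre-selection that
  empties a test set (the error names the criteria and removal counts).

## Problem sizes

The test suite and the acceptance script size their simulations for a
single CPU: contrast recovery uses 50 phantoms at the default
128×128×64 geometry; metric-oracle equivalence uses 200 random mask pairs
on ≤ 12³ grids where O(n²) oracles are exact and cheap; the end-to-end
study runs a 30-case cohort (20 high-contrast, 10 zero-contrast) and the
margin-smoothing experiment 50 pred/ref pairs. Pipeline-level tests use a
64×64×32 grid at 2×2×2.5 mm, a scaled-down cohort with the same
statistical structure.

## Known limitations

* NIfTI only; DICOM/RTSTRUCT conversion is upstream tooling.
* The directional margin reduction is a declared construction, not a
  claim about how any treatment-planning system edits margins.
* The location criterion's 95% containment threshold stands in for a
  judgment call that is manual in clinical practice.
* The visibility background excludes bone only; in anatomy with air
  adjacent to the cavity the background mean would be biased and an
  additional exclusion rule would be needed.
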