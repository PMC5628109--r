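---
title: "Automatic calcium scoring in attenuation-correction CT: models and methods"
author: "cacscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic calcium scoring in attenuation-correction CT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cacscore)
```

This vignette explains the science implemented by `cacscore`: the scoring
model and its assumptions, the tunable parameters and their defaults, the
statistics used to evaluate agreement between scoring methods, what the
synthetic phantom does and does not emulate, and the numerical and design
choices made where the problem left them open.

## The scoring model

Coronary artery calcium (CAC) is quantified on CT by the Agatston
convention: on each axial slice, contiguous tissue at or above 130
Hounsfield units (HU) contributes its area in mm² multiplied by a weight
determined by the slice's peak attenuation — 1 for 130–199 HU, 2 for
200–299, 3 for 300–399, 4 for 400 and above — summed over slices and
lesions. The companion volume score is simply the physical volume of all
lesion voxels. Patients are stratified into five cardiovascular-risk
categories by the Agatston score: 0, (0, 10], (10, 100], (100, 400],
(400, ∞).

Two modelling commitments follow from this definition and are fixed
throughout the package:

* **Inclusive threshold.** A voxel at exactly 130 HU is calcium: the first
  weight band starts at 130, so the comparison is `HU >= 130`.
* **No rounding.** Clinical software sometimes rounds per-lesion
  contributions; with sub-mm² pixels the score is naturally fractional, and
  this implementation never rounds. Scores such as 10.935 are meaningful and
  category boundaries are evaluated on the exact value. The zero/positive
  distinction — clinically the most important one — is therefore exact.

Attenuation-correction CT (CTAC) and dedicated calcium-scoring CT (CSCT)
both use 3 mm slices here, so no slice-thickness renormalization of the
score is applied.

## Candidate extraction

Candidates are maximal connected components of supra-threshold voxels under
a 3D neighborhood of order 6, 18 or 26. The default is 26 (full
neighborhood): motion in non-gated scans smears lesions into fragments that
touch diagonally, and the full neighborhood keeps them together. The order
is a parameter because the choice is conventional, not principled.
Single-voxel components are discarded: at CTAC noise levels (~25 HU), a
single bright voxel cannot be distinguished from a noise excursion
(a ~3.6 sd event against a 20–50 HU background is expected several times
per scan on a ~37k-voxel grid).

No bone or aorta exclusion happens at this stage. The two-class design puts
all of the rejection burden on the classifier, which sees bones and aortic
calcifications as labeled negatives.

## Features

Each candidate is described by four blocks (21 features by default, schema
version `cac-features/1-s1,2,4`):

* **Volume**: voxel count and physical volume (mm³).
* **Shape**: the eigenvalues λ1 ≥ λ2 ≥ λ3 of the covariance of member-voxel
  positions give the ratios r21 = λ2/λ1, r31 = λ3/λ1, r32 = λ3/λ2.
  Positions are taken in millimetres, not voxel indices, so 3 mm slices do
  not make every lesion look flat. A zero denominator (collinear or planar
  candidates) defines the ratio as 0. The ratios are invariant to rotation
  and to uniform scaling of the grid.
* **Intensity**: max, mean and sd of the member voxels, plus max and mean
  sampled over member voxels of the volume smoothed at σ = 1, 2, 4 mm.
  Physical-unit σ is converted per axis to voxel units, so smoothing is
  isotropic in space on anisotropic grids. The multi-scale block measures
  how conspicuous a candidate remains under blur, which separates compact
  calcium from streaks. The scales and the statistics list are
  configurable; the defaults cover the lesion size range of interest
  (sub-voxel to ~7 mm).
* **Location**: distance (mm) from the candidate centroid to the nearest
  point of each labeled coronary centerline (RCA, LAD, LCX) and of their
  union, plus the centroid in heart-centered coordinates normalized by the
  heart's half-extent per axis. Location is the single most discriminative
  block: coronary calcium lies on the coronary tree; vertebral bone and
  aortic-wall calcium do not.

## The coronary-tree estimate

Location features need an estimate of where the coronary tree runs in the
subject scan. The package maps a template — a reference volume, its heart
mask, and three labeled centerline polylines — into the subject by an
affine transform fitted to heart-region intensity moments: the voxels in a
soft-tissue/blood HU band (default 35–90 HU, above fat and far below
calcium) are collected in both scans, and their centroid and per-axis
standard deviation are matched by a per-axis scaling plus translation. The
same band-threshold definition is used on both sides, so a subject that
*is* the template (possibly translated) maps exactly.

Rotation is deliberately not estimated. Axial CT is acquired in a fixed
supine convention, so residual rotation is small; and a principal-axes
rotation fit has sign/ordering ambiguities that make it fragile on
near-spherical hearts. The cost is a registration error of roughly 1–2 mm
under realistic per-patient anatomy shifts, which is small against the
~10 mm scale that separates coronary from non-coronary candidates.

Distances to the tree are computed analytically as exact point-to-polyline
distances at the candidate centroid, rather than by interpolating a
precomputed grid distance transform — exact where the interpolated map
would be approximate. A grid `distance_map()` is provided for inspection
and testing.

## Classifier

An ensemble of 250 extremely randomized trees (Extra-Trees) classifies
candidates: no bootstrap (each tree sees all examples), a random split
threshold per candidate feature, `sqrt(p)` features tried per node, trees
grown to purity. The tree count follows the scoring pipeline convention;
the remaining hyperparameters are the algorithm's canonical defaults. The
decision threshold on the ensemble's CAC-vote fraction is 0.5 by default
and is a parameter — reported detection metrics always correspond to a
stated threshold.

Evaluation uses tenfold cross-validation that partitions *patients*:
candidates of one patient are never split between training and test, and
every candidate is scored exactly once, by a model that never saw its
patient. Training is deterministic given example order, tree count and
seed. Candidates are labeled against reference masks by the weakest useful
rule — one shared voxel — because any stricter overlap rule would need a
lesion-correspondence model that the two-class design does not require.

## Agreement statistics

* **Linearly weighted Cohen's κ** for ordinal risk categories, with weights
  `w_ij = 1 − |i−j|/(k−1)`: κ = (Po_w − Pe_w)/(1 − Pe_w). The standard
  error is the large-sample variance of weighted κ (Fleiss–Cohen–Everitt),
  and the 95% CI is Wald. The CI method is recorded in the result object
  because published κ CIs are often produced by unnamed calculators;
  comparisons should be made on κ itself.
* **Accuracy** (observed agreement) with the Wilson score interval — chosen
  over the Wald interval for its behaviour near 0 and 1.
* **ICC(A,1)**: two-way, absolute-agreement, single-measure intraclass
  correlation, `(MSR − MSE)/(MSR + (k−1)MSE + (k/n)(MSC − MSE))`, with the
  F-based McGraw–Wong interval. Absolute agreement (not consistency) is the
  right form when a systematic score offset between methods must count as
  disagreement.
* **Wilcoxon signed-rank**, two-sided, zeros dropped, tied ranks averaged.
  For ≤ 25 informative pairs the exact null distribution of the rank sum is
  computed by dynamic programming over the (half-integer) rank lattice —
  valid under ties, where the standard exact algorithm refuses; above 25
  pairs the normal approximation with continuity correction is used.
* **z-comparison** of two κs or accuracies: z = (e1 − e2)/√(se1² + se2²),
  treating the samples as independent. When the two estimates share
  patients this is conservative in neither direction a priori; it is kept
  because it is the convention for this comparison, and the assumption is
  documented here.
* **Detection metrics** per scan: a detected lesion is a true positive if
  it overlaps any reference lesion by ≥ 1 voxel; lesion and volume
  sensitivity are averaged over scans that have reference calcium, while
  false-positive counts and volume are averaged over all scans (zero-CAC
  scans carry information about specificity only).

### Rank-based category assignment

Scores from different scan types differ systematically (partial volume,
motion, tube voltage), but patient *ranking* is far more stable. To compare
categorizations across scan types, the reference categorization fixes the
per-category quotas; test patients, sorted by ascending score, fill those
quotas from the bottom. Two tie rules complete the definition, chosen here
because the underlying convention leaves them open:

* a score of exactly 0 always maps to category 1, even when this overflows
  the quota — zero calcium is qualitatively different from low calcium, and
  collapsing zeros preserves that distinction;
* a group of equal nonzero scores takes the single category holding the
  majority of the group's quota slots, the lower category on a split.

With many zero scores in the test cohort the level-1 count exceeds its
quota and the categories immediately above are depleted from below — the
column pattern visible whenever a coarse, noisy scan type is ranked against
a cleaner reference.

## The synthetic phantom

The phantom exists to exercise operators with analytic ground truth, not to
look like a patient. A parametric thorax (soft tissue 20 HU, lungs −800,
heart/blood 50, vertebra 700) carries three coronary centerlines on the
heart surface, spherical-paraboloid lesions placed along them, and
distractor calcifications on the aortic wall. One rendering on the fine
grid (0.3375 mm in-plane — exactly a quarter of the 1.35 mm CTAC pixel — 3
mm slices, 16×192×192 voxels over a 48×64.8×64.8 mm field) serves both
scan types:

* **CSCT**: the fine rendering plus Gaussian noise (sd 10 HU);
* **CTAC**: anisotropic Gaussian motion blur (σ 1.5 mm along z and y,
  0.75 mm along x — a conservative stand-in for several mm of cardiac
  excursion during a non-gated acquisition), then 4× area-weighted in-plane
  downsampling, then Gaussian noise (sd 25 HU).

Partial-volume effects arise from the downsampling; through-plane motion
blur mixes 3 mm slices and is the dominant mechanism by which non-gated
truth scores fall below gated ones (weight-band drops at the 400/300/200 HU
boundaries), reproducing the systematic score loss seen when comparing
scan types. Ground truth is defined as what a perfect scorer would measure
on the *noise-free* acquisition of each scan type — for CTAC this includes
the deterministic motion blur.

Truth masks follow the same conventions as the scoring pipeline: voxels at
or above 130 HU, single-voxel fragments dropped, and masks made disjoint by
assigning voxels in overlapping capture regions to the nearest lesion
centre. Geometry enforces clearances (lesion separation ≥ 6 mm surface to
surface; coronary tree ≥ 8 mm from any distractor's supra-threshold
region), so a lesion's truth mask can never swallow a neighbour or a
distractor, and noise-free automatic scoring equals truth exactly — a
property the test suite asserts end to end.

Cohort defaults (fixed as the package's study conditions): 10% of patients
with zero CAC; 1–6 lesions per positive patient, radius uniform in
2.2–3.5 mm and peak uniform in 400–800 HU — large and dense enough to
remain conspicuous on a 3 mm / 1.35 mm non-gated grid (the single-pair API
accepts any peak ≥ 130 for testing threshold behaviour); 0–3 aortic-wall
calcifications per patient on the side of the aorta facing away from the
heart; per-patient heart position jitter of ±2–3 mm and size scaling of
±6%. Seeded experiments use 20-patient cohorts: large enough for tenfold
patient-level cross-validation and stable cohort means, small enough that
the full pipeline runs in well under a minute per cohort.

What the phantom does **not** emulate: beam hardening, kVp-dependent HU
shifts, metal and stent artifacts, anatomical shape variation, breathing
motion, and the continuum of faint sub-130 HU plaque. Passing phantom tests
therefore demonstrates that the operators are implemented correctly and
that the pipeline is coherent end to end — not that clinical performance on
real CTAC data would match.

## Numerical choices and degenerate inputs

* HU values outside [−1024, 3071] are clipped on volume construction with a
  warning (low-dose reconstructions overshoot; rejecting them would refuse
  real data).
* NIfTI stores voxel spacing as 32-bit floats; spacing round-trips to
  ~1e-8 relative precision (MetaImage round-trips exactly). Voxel data are
  written as 64-bit floats and round-trip exactly.
* Eigenvalue ratios define 0/0 as 0; eigenvalues are clamped at 0 and a
  relative tolerance of 1e-9 guards the λ2 denominator.
* κ is undefined when weighted chance agreement is 1 (all mass in one
  cell); ICC is undefined with zero variance everywhere; the signed-rank
  test is undefined when all differences are zero. All three raise error
  flags, and the experiment orchestrator converts them to typed
  `undefined_statistic` results rather than aborting a report.
* A cohort with only one candidate class (e.g. all-zero CAC) cannot train a
  classifier; the orchestrator falls back to labeling every candidate with
  the only observed class and reports the degenerate statistics flags.
* Candidate ordering (decreasing volume, ties by first voxel in
  lexicographic (z, y, x) order) and fold assignment (seeded shuffle of
  patient ids, round-robin) are fully deterministic, so identical inputs
  and seeds give byte-identical reports.

## Known limitations

* The coronary-tree estimate is a single-template affine fit; it cannot
  follow anatomical variation of the coronary course, only global position
  and size. On real data the template should come from a segmented
  reference subject, and the residual registration error inflates the
  location features' noise floor.
* The κ standard error assumes independent sampling of subjects; the
  z-comparison additionally assumes independent samples.
* Extra-Trees probabilities are vote fractions, not calibrated
  probabilities; the 0.5 threshold is an operating point, not an optimum.
* Agatston weights are a step function of peak HU, so scores are
  discontinuous in the input; small noise can move a slice across a weight
  boundary, which is a property of the score, not of the implementation.
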