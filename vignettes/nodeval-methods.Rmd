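---
title: "Evaluating lymph-node localization and segmentation with nodeval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating lymph-node localization and segmentation with nodeval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The evaluation problem

Automated cervical lymph-node segmentation models return a binary mask of
node tissue on a 3D CT volume. Judging such a model against a manual
ground-truth segmentation is not a single-number problem: clinicians care
about *localization* (was each node found at all?), *segmentation quality*
(how well is a found node delineated?), and how both vary with node size
(the RECIST 1.1 short-axis diameter, SAD) and metastatic status. Confluent
("bulky") nodal disease makes one-to-one matching between predicted and
ground-truth nodes ill-defined, so the pipeline implemented here is
deliberately ground-truth-centric.

`nodeval` implements that evaluation pipeline end to end, plus a synthetic
phantom-cohort generator so every stage can be exercised and verified
without patient data.

## The per-scan pipeline

For one scan, with a ground-truth mask and a predicted mask on the same
voxel grid (anisotropic spacing in mm, never resampled), the stages run in
a fixed order:

1. **Instance extraction.** Connected-component analysis of each binary
   mask (default 26-connectivity, the most permissive merging, so
   diagonally touching nodes form one instance — which is also the correct
   representation of bulky disease). Components are labelled in
   deterministic raster order.
2. **Morphometry.** Each instance gets a voxel count, a volume in mm³ and
   a mask-based SAD (below).
3. **Size filter.** Predicted instances with SAD < 4.5 mm are removed
   *before* any matching; the boundary value is kept (the rule removes
   strictly smaller instances). This mirrors the post-processing of the
   evaluated segmentation software, which treats such blobs as noise.
4. **Matching.** Per ground-truth node the *sensitivity*
   |GT<sub>i</sub> ∩ Pred| / |GT<sub>i</sub>| is computed against the
   filtered prediction foreground; a node is *localized* when sensitivity
   ≥ 0.4 (boundary inclusive). Per predicted instance the fraction of its
   voxels on ground-truth foreground is computed; an instance is a *false
   positive* when that fraction is < θ<sub>FP</sub> = 0.4. There is no
   bijective assignment: one merged prediction may localize several nodes.
5. **Detection metrics.** Recall = localized/GT nodes; precision =
   non-FP/predictions; F1 = harmonic mean; FP count and FP size
   distribution (including the ≥ 10 mm sub-count). With zero predictions,
   precision is 1 on an empty scan and missing otherwise — undefined
   values are always reported as missing, never as zero.
6. **Filtered segmentation metrics.** Missed ground-truth instances and FP
   predictions are removed from their masks, and the global Dice
   coefficient and average Hausdorff distance are computed on the filtered
   pair, so they measure delineation quality where detection succeeded.

All thresholds (4.5 mm, 0.4, 0.4, the 5/10/15 mm bin edges, α = 0.01,
connectivity) live in `eval_config()` and are echoed into every report.

## The SAD estimator

RECIST 1.1 measures nodal lesions by the short-axis diameter on the axial
plane, but a mask-based analogue of the radiologist's caliper measurement
has to be pinned down. `compute_sad()` works per axial slice: the slice's
*long axis* is the maximal point-pair distance over in-plane voxel centres
(the maximal caliper, computed on the convex hull; the first maximal pair
wins ties, making the measurement deterministic), and the *short axis* is
the slice's maximal extent perpendicular to that direction. The node's SAD
is the maximum of the per-slice short axes over all slices it occupies.

Centre-to-centre extents systematically under-measure physical extents by
one voxel, so one in-plane voxel dimension is added, and the result is
floored at one in-plane voxel: a single voxel measures 1 mm at 1 mm
in-plane spacing, and a digital sphere of diameter d measures d within one
in-plane voxel at any slice spacing (verified for spacings (1,1,1),
(1,1,2) and (0.7,0.7,2.5) in the test suite). Taking the maximum over
slices rather than the SAD at the largest-area slice is a deliberate
choice: it is deterministic and stable against which slice happens to cut
the node's equator.

Two alternative estimators — the minimal Feret width and a
moment-matched-ellipse minor diameter — are available behind
`compute_sad(method=)` and are documented as non-canonical.

## Average Hausdorff distance

The "average Hausdorff distance" is implemented as the symmetric average
surface distance: the mean, over boundary voxels of one mask, of the
distance in mm to the nearest boundary voxel of the other, averaged over
both directions. A boundary voxel is a foreground voxel with at least one
background 6-neighbour (the volume face counts as background). Distances
are Euclidean in physical mm under the native anisotropic spacing,
computed with an exact separable distance transform and verified against
an exhaustive pairwise-distance oracle on small volumes. Sub-millimetre
cohort values are only achievable by an averaged surface metric — a
maximum-based Hausdorff cannot drop below the slice spacing under any
realistic boundary noise — which is why the averaged form is the default;
directed variants are available via `average_hausdorff(variant=)`. The
metric is undefined (missing, with a warning) when either filtered mask is
empty.

## Cohort aggregation and statistics

`aggregate_cohort()` produces the stratified cohort table (node counts,
recall and mean per-node sensitivity by SAD bin × metastatic status; bins
are left-closed/right-open on edges 5/10/15 mm) and both of:

* **macro recall** — the per-scan mean of scan recalls, and
* **micro recall** — pooled over all nodes (identically the node-count
  weighted mean of the bin recalls, an invariant the tests assert to
  machine precision).

The two genuinely differ and are always reported under separate labels.
Mean per-node sensitivity in the strata includes *all* nodes — missed
nodes contribute their sub-threshold sensitivity — because sensitivity is
used as a continuous per-node quality measure; a localized-only view is
available through `sad_sensitivity_data(localized_only = TRUE)`.

The statistical battery mirrors standard practice for such cohorts: a
Shapiro–Wilk normality screen (nonparametric tests are used because node
metrics are far from normal), Kruskal–Wallis comparisons at α = 0.01 of
localization and sensitivity between metastatic and non-metastatic nodes
and across SAD bins, post hoc pairwise rank tests (raw p-values by
default, Holm available — raw pairwise reporting matches how such cohorts
are usually published), and Pearson correlations between SAD and
sensitivity, overall and restricted to nodes > 10 mm. The unit of analysis
for the recall comparison is the per-node 0/1 localized indicator; a
per-scan-recall alternative sits behind
`aggregate_cohort(recall_test_unit = "scan")`. Both choices are recorded
in the report metadata.

## The synthetic phantom cohort

The generator (`cohort_config()`, `sample_gt_scan()`) emulates the
statistical structure of a 125-scan head-and-neck CT cohort with 3656
ground-truth nodes:

* node count per scan ~ Poisson(29.2);
* each node metastatic with probability 544/3656;
* status-conditional SADs from truncated log-normal distributions, with
  the log-scale location solved numerically so the truncated means are
  5.0 mm (non-metastatic, truncated at the observed maximum 23.3 mm) and
  11.3 mm (metastatic, maximum 57.9 mm); the spreads (sdlog 0.30 / 0.55)
  were chosen once to roughly reproduce the reference size-bin occupancy;
* occasional touching-node clusters (probability 0.05 that a node is
  placed in contact with the previous one), which the instance extractor
  correctly merges;
* central necrotic cores (15% of node volume) in metastatic nodes
  ≥ 15 mm, reflecting the high specificity of central necrosis for nodal
  metastasis in head and neck cancer.

Nodes are random-orientation digital ellipsoids on a 128×128×64 grid at
(1, 1, 2) mm spacing — large enough to hold the biggest observed
metastatic node, small enough that a full 125-scan cohort simulates and
evaluates in about two minutes. Ellipsoids are *not* realistic node
geometry; they are used because their SAD and volume are analytically
controllable, which is what a verification phantom must offer. Node
centres snap to the voxel grid and each node's in-plane semi-axes are
calibrated by measure-and-adjust iterations so its realised SAD (as
measured by `compute_sad()`) lands within about half an in-plane voxel of
the sampled target, with a hard floor (`sad_floor_mm`, 4.55 mm) that keeps
every realised node above the evaluation's 4.5 mm prediction filter. The
target-SAD distributions are truncated below at 4.7 mm, mirroring the
annotation protocol that only segmented nodes of roughly 5 mm and larger;
nodes measuring just under 5 mm populate the `<5` bin exactly as in the
reference cohort, where annotation-time inclusion and evaluation-time SAD
are independent measurements.

### The degradation model

`degradation_config()` turns a phantom into a plausible imperfect
prediction with four failure modes:

* **size-dependent whole-node misses** — each ground-truth instance is
  dropped with its measured-SAD bin's miss probability (defaults
  0.28/0.21/0.33/0.64, one minus the reference per-bin recalls). Misses
  are drawn per instance *before* boundary degradation, so realised
  per-bin recall is binomial with known success probability — the
  structure the verification suite relies on;
* **boundary errors** — surviving nodes are dilated (p = 0.3) or eroded
  (p = 0.2) in-plane by one voxel. Erosion only applies to nodes ≥ 9 mm:
  below that, a one-voxel erosion could push sensitivity under the 0.4
  localization threshold and silently bias the recall calibration;
* **necrosis drop-out** — with probability 0.8 the necrotic core is left
  out of the prediction of a necrotic node, reproducing the
  characteristic failure on large metastatic nodes while leaving the
  node localized (the shell still covers well over 40%);
* **false positives** — Poisson(6.5) background ellipsoids per scan with
  truncated log-normal sizes of mean 5.3 mm. The FP population is
  deliberately the *post-filter* stream (sizes truncated below just above
  4.5 mm), because the reference FP rate and mean size are counted after
  size filtering; FPs are placed clear of ground truth so they classify
  as false positives and never merge into real nodes.

A residual guard dilates a surviving predicted component that would fall
under the size filter (possible only after unusual erosion) until it
clears 4.5 mm. `expected_metrics()` states the closed-form expectations —
per-bin recall 1 − miss probability, FPs/scan equal to the Poisson rate —
and the acceptance suite shows the full simulate→evaluate loop recovers
them on the default 125-scan study (observed: every bin within 0.02,
FPs/scan within 0.05 of 6.5 at the default seed).

### What the phantom does and does not establish

Passing the recovery tests shows the *pipeline* is correct: instances,
SADs, matching, filtering and aggregation faithfully measure a cohort
whose ground truth is known. It does not show that real CT segmentation
behaves like the degradation model: real boundary errors are milder and
more structured than random one-voxel morphology, real FPs sit on
anatomically confusable structures (vessels), and dental-artifact
failures are not modelled at all. Consequently the phantom's filtered
Dice (≈ 0.89) and average Hausdorff (≈ 0.26 mm) are better than the
reference cohort's 0.73 / 0.88 mm — the phantom is calibrated to the
detection statistics, not to delineation noise. Boundary-error parameters
would need independent calibration for that.

## Numerical choices and degenerate inputs

* Ties in the long-axis search: first maximal pair in scan order wins.
* A one-point slice contributes one in-plane voxel; collinear slices fall
  back to all points when the hull degenerates.
* Instance labels must be consecutive 1..K; non-consecutive label files
  are rejected unless `relabel = TRUE` (fail loudly on malformed input).
* Empty masks: Dice is 1 for two empty masks and 0 for exactly one;
  surface distance is missing with a warning.
* Metadata rows without a matching instance are dropped with a warning;
  instances without metadata default to non-metastatic with a warning.
* The Shapiro–Wilk screen uses a deterministic evenly-spaced subsample
  above n = 5000 (the statistic's defined range); a constant sample is an
  error.
* All cohort randomness flows from one seed through per-scan derived
  seeds, so cohorts regenerate byte-identically.

## Problem sizes used by the test suite

The verification suite runs the complete default study — 125 simulated
scans, ≈ 3400–3700 nodes — once for the parameter-recovery checks, the
metric-oracle equivalence on one hundred random ≤ 12³ volumes against
exhaustive brute-force oracles, SAD checks on digital spheres and
ellipsoids at three anisotropic spacings, and degradation-monotonicity
and necrosis-effect checks on 3–6-scan cohorts. These sizes were chosen
so the statistical assertions have the power they claim (≥ 200 nodes in
the dominant bins) while the whole suite stays comfortably interactive.

## Known limitations

* The SAD estimator is caliper-based on voxel centres; for strongly
  concave in-plane cross-sections the maximal caliper direction can
  differ from a radiologist's chosen long axis. Real nodes are convex to
  mildly elliptic, where the estimator is exact to digitization.
* The false-positive threshold θ<sub>FP</sub> has no published
  definition; 0.4 (symmetric with localization) is a declared default,
  not an inferred fact, and is configurable.
* Sensitivity-vs-SAD correlations on phantom cohorts emerge from the
  size-dependent miss and necrosis mechanisms only; they are not
  calibrated quantities.
* The generator places ellipsoids with small safety gaps; spatial
  clustering beyond deliberate touching pairs, anatomical node levels and
  image intensities are out of scope.
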