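---
title: "Methods: multimodal graph analysis of the switching motor network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal graph analysis of the switching motor network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Overview

`switchnet` reconstructs and compares two views of the same 22-node brain
network — the "switching motor network" of regions engaged when people switch
between competing motor task sets (medial frontal cortex, anterior cingulate,
basal ganglia, insula, lateral prefrontal, premotor, parietal and cerebellar
nodes). The **functional** view is built from regional fMRI time series; the
**structural** view from deterministic diffusion-tensor tractography. Both
are scored with the same graph metrics and compared at the group level
(traumatic brain injury patients vs healthy controls), with a median-split
linear discriminant analysis asking whether connectivity degree predicts
good vs poor task-switching performance.

Because no patient data are redistributable, the package carries a
first-class synthetic-cohort generator with known ground truth, so that every
stage — estimation, tractography, metrics, statistics, classification — is
testable end to end.

# Node model

All matrices are indexed by a fixed, ordered atlas of 22 spherical regions
of interest (ROIs), radius 10 mm by default (`make_roi_atlas()`). Node
*identity and order* are the contract: every downstream matrix uses the same
ordering. The shipped coordinates are a documented synthetic fixture with
plausible MNI-space locations for each label — the analysis is driven by the
node set, not by the exact millimetre positions — and any atlas TSV
(`name, x_mm, y_mm, z_mm, radius_mm`) can replace them via `read_atlas()`.

# Functional connectivity

For each subject, a T x 22 panel of regional mean time series is reduced to
a partial-correlation matrix (`partial_correlation_matrix()`): entry (i, j)
is the correlation between nodes i and j *conditional on all remaining 20
nodes*, computed from the inverse sample covariance \(\Omega\) as
\(r_{ij} = -\Omega_{ij} / \sqrt{\Omega_{ii}\,\Omega_{jj}}\). This removes
shared drive that inflates marginal correlations. Numerical notes:

* The inversion requires T > N; for short panels a ridge
  (`ridge * mean(diag(S)) * I`) is available and the error message says so.
* The estimator is validated in the test suite against an independent
  regression-residual oracle (correlating the residuals of regressing i and
  j on all other nodes) to 1e-8.

Signed partial correlations are mapped to non-negative edge weights before
graph analysis. The default (`zero_negatives`) zeroes negative entries;
shortest-path-based metrics require non-negative weights, and zeroing
negatives is the standard choice for correlation networks. An `absolute`
mode keeps magnitudes instead. Binary networks set every strictly non-zero
weight to one (`binarize()`); because continuous partial correlations are
almost never exactly zero, this makes the binary functional graph
near-complete, so an optional magnitude threshold (default off) is provided
for users who want sparser binary graphs. How the original analyses obtained
non-complete binary functional graphs is not documented anywhere we could
follow; the threshold is a pragmatic option, not a reconstruction of that
procedure.

# Structural connectivity

Tractography (`track_streamlines()`) is deterministic streamline
integration through the tensor field:

* seeds on a 2 mm isotropic grid, restricted to voxels with FA >= 0.2;
* Euler steps of 1 mm along the principal eigenvector of the *trilinearly
  interpolated* tensor (interpolate components, then eigen-decompose per
  step) — appropriate for sub-voxel stepping through multi-mm voxels;
* eigenvector sign continuity: each step's eigenvector is flipped toward
  the previous direction; the seed's two half-tracks start from the seed
  voxel eigenvector and its negation, and are concatenated;
* termination on interpolated FA < 0.2, a turning angle strictly exceeding
  45 degrees between consecutive steps, leaving the volume, or a 2000-step
  safety cap (2 m of track); the reason is recorded per half-track.

Connectivity (`count_matrix()`) counts streamlines passing through both ROI
spheres of a pair — pass-through of any vertex, not endpoint termination,
because 10 mm spheres centred on grey-matter peaks are rarely exact
termination sites. `fa_weight_matrix()` instead weights each connection by
the mean over connecting streamlines of their mean interpolated FA.
`normalize_structural()` offers `raw` counts (default) and a
`total_fraction` mode (upper-triangle sums to 1); raw streamline counts have
an arbitrary scale that depends on seed density, so cross-study comparisons
should prefer the fraction mode or binary graphs.

The FA of a tensor uses the standard eigenvalue formula with eigenvalues
clamped at zero, and the zero tensor is assigned FA 0.

# Graph metrics

On each of the four per-subject networks (weighted/binary x
functional/structural) the package computes, per node: degree (count of
non-zero links), strength (sum of weights), local efficiency (global
efficiency — mean inverse shortest-path length over ordered pairs — of the
subgraph induced by the node's neighbours, 0 for nodes with fewer than two
neighbours), and betweenness centrality (fractional shortest-path
membership, Brandes' algorithm with exact tie counting). Conventions, chosen
to match the Brain Connectivity Toolbox:

* weight-to-length mapping is 1/w for weighted graphs, 1 for binary edges;
* betweenness is summed over unordered pairs and left unnormalized (raw
  counts);
* the network-level summary of each metric is the arithmetic mean over the
  22 nodes, giving one value per subject per metric.

Shortest paths and betweenness are delegated to igraph; local efficiency is
composed on neighbour-induced subgraphs in-package. All three are tested
against exhaustive enumeration of simple paths on random graphs with up to 8
nodes.

Hubs (`identify_hubs()`) are nodes whose betweenness, averaged across the
subjects of a group, exceeds the across-node mean by more than two
across-node standard deviations (n-1 denominator, strict inequality), per
group and modality.

# Group statistics

* Two-sample t-tests (pooled variance by default, Welch optional) compare
  per-subject network summaries and behavioral scores between groups.
* Reaction times from the task-switching paradigm are analysed with a 2 x 2
  mixed-design ANOVA (between: group; within: switch vs repeat, or global vs
  local cue), fitted through the standard error-stratum decomposition.
  Each within factor is analysed separately.
* Structure–function coupling is assessed with Pearson correlations between
  subjects' structural and functional network summaries, per metric and
  within each group, plus a nodal variant correlating nodal degree across
  subjects (one row per ROI).
* p-values are two-sided and uncorrected throughout, matching the reporting
  style the pipeline mirrors; reaction-time summaries use correct trials
  only.

# Median-split classification

Subjects are split at the median of their switch-block accuracy; scores
strictly above the median are "good" performers and ties go to the lower
class. A two-class linear discriminant (equal-covariance Gaussian rule,
proportional priors) is fitted on (1) structural network-summary degree,
(2) functional network-summary degree, (3) both jointly, and evaluated by
resubstitution — matching the reporting style of the analyses this package
reimplements; a clearly-labelled leave-one-out variant
(`lda_classify_loo()`) is provided as an extension. Reports carry the
confusion counts, sensitivity (good performers as positives — a documented
choice, since polarity is conventionally left unstated), specificity,
overall accuracy, and Wilks' lambda = det(within scatter)/det(total
scatter), which the single-feature case reduces to
\(1/(1 + t^2/(n-2))\) — an identity the tests verify to 1e-10.

# The synthetic cohort

`make_cohort()` builds a default cohort of 17 patients and 16 controls, the
study conditions the pipeline targets. Components:

* **Functional panels.** Zero-mean multivariate normal draws with a known
  sparse precision matrix (`default_precision()`: unit diagonal, ring plus
  cross-links at -0.18), so ground-truth partial correlations are available
  in closed form. The patient group scales off-diagonal precision entries
  by 1.5 (re-projected to positive definite if needed), planting a
  functional-coupling increase with patients above controls. The default
  panel length is T = 200 volumes — a typical event-related run length;
  the real run length is not documented, so it is configurable.
* **Tensor phantoms.** Near-isotropic background (FA well below the 0.2
  tracking threshold, with 2% seeded eigenvalue jitter) plus cylindrical
  anisotropic tubes (principal eigenvalues 1.7/0.2/0.2 x 1e-3 mm²/s,
  FA ≈ 0.87) along seven default ROI-pair bundles forming a connected
  medial-frontal/prefrontal circuit with one triangle, so the planted
  structural topology supports non-trivial local efficiency and
  betweenness. Per subject, each bundle
  is kept with probability 0.85 and the tube radius is drawn from
  U(3, 5) mm — anatomical variability without which between-subject
  structural statistics would be degenerate. The distribution is identical
  in both groups: no structural group effect is planted, matching the null
  structural findings the pipeline mirrors.
* **Behavior.** The task schedule is fixed: 24 trials per pure block and 49
  switch-block trials whose cued dimension alternates every other trial
  (local, local, global, global, ...). The first trial after a cue change
  is a switch trial, the second a repeat; the block's first trial belongs
  to neither category (the pairwise-alternation design leaves first-trial
  handling unstated, so this is fixed and documented here). Reaction times
  are normal per condition, truncated at zero by rejection; default means
  come from the published group summaries (patients: 676/641 ms
  switch/repeat; global 597 ms vs local 634 ms), with SDs reconstructed
  from the printed standard errors. Controls are given a small (10 ms)
  switch cost so the group-by-switch interaction is planted in the patient
  direction. Accuracy is Bernoulli, 0.88 (patients) vs 0.95 (controls).
* **Reproducibility.** Per-subject seeds are derived from the master seed
  by a fixed affine hash below 2^31; identical configurations reproduce
  cohorts byte-identically on disk.

What the generator does **not** emulate: scanner physics, hemodynamics,
head motion, lesions, raw diffusion-weighted signals, curved or crossing
fiber anatomy, and spatially structured noise. Passing tests demonstrate
that the algorithms are implemented correctly and recover planted structure
under these idealized conditions — not that they would produce identical
findings on real clinical data.

# Problem sizes and tolerances used by the test suite

The suite exercises: partial-correlation recovery at T = 20 000 (tolerance
0.03 against the closed form); oracle equivalence on 200 random panels
(<= 1e-8) and 200 weighted plus 200 binary random graphs with at most 8
nodes (exhaustive path enumeration, <= 1e-9); planted-bundle recovery on 20
random well-separated phantoms (exact binary equality); detection of the
planted coupling increase in at least 80% of 50 cohort replicates; t-test
and mixed-ANOVA type-I error calibrated to 0.05 ± 0.02 over 1000 null
replicates at n = 16 per group; and straight-line tractography recovery to
1e-6 with audited FA/angle termination. End-to-end pipeline checks run on
reduced cohorts (3-6 subjects, 3 mm phantom voxels, T = 80) chosen to keep
the default suite fast while exercising every stage; `scripts/acceptance.R`
runs the full default conditions (33 subjects, 2 mm voxels).

# Known limitations

* The fixture coordinates are synthetic; spatial results (which bundles are
  recoverable, sphere overlaps in the basal ganglia cluster) depend on them.
* Raw streamline counts and therefore structural strength have a
  seed-density-dependent scale; only comparisons within a fixed
  configuration are meaningful.
* The binary functional graph is near-complete under the strict non-zero
  rule (see above).
* Resubstitution classification accuracy is optimistic by construction;
  use the leave-one-out variant for generalization estimates.
* Tractography is single-tensor and deterministic: crossing or kissing
  fibers are outside the model class.
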