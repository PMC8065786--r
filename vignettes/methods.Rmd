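---
title: "Resting-state connectivity group analysis: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resting-state connectivity group analysis: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(restconn)
```

## The analysis problem

restconn implements a complete region-of-interest (ROI) resting-state
functional-connectivity comparison between two cohorts — in the motivating
design, a group of experts (n = 21) and a group of controls (n = 23) scanned
for 420 volumes at TR = 2 s — together with a synthetic cohort generator
that makes every stage testable against known ground truth.

The chain is:

1. **Motion quantification and censoring.** Frame-wise displacement (FD) is
   the sum of absolute volume-to-volume changes in the six rigid-body
   realignment parameters, rotations converted to arc length on a 50 mm
   sphere. After dropping the first four volumes, any volume with
   FD > 0.5 mm is flagged. The cohort's worst mover sets a common removal
   count: every participant loses that many volumes (their flagged volumes
   first, then their highest-FD remaining volumes), so all subjects
   contribute the same number of samples to every downstream estimate.
2. **Nuisance regression (CompCor).** The top five principal-component time
   series of the white-matter voxel bank and five from CSF, plus the six
   linearly detrended motion parameters, an intercept and a linear trend,
   are regressed out of every ROI series by ordinary least squares.
3. **Temporal filtering.** A zero-phase (forward–backward) Butterworth
   bandpass at 0.01–0.1 Hz isolates the low-frequency fluctuations that
   define resting-state connectivity.
4. **Connectivity.** Each ROI contributes one representative series (the
   first principal component of its voxels when voxel data are supplied,
   sign-aligned with the ROI mean); all pairwise Pearson correlations over
   the 112-region parcellation are Fisher-transformed (z = atanh r),
   giving 6216 edge features per participant.
5. **Group inference.** Each edge is tested with a pooled-variance
   two-sample t statistic whose null distribution is built by permuting
   group labels (default 10,000 replicates); edges with p < 0.01
   (uncorrected) are retained and reported in direction blocks. Per-group
   Pearson correlations between each significant edge and the behavioural
   score are computed, uncorrected, as a descriptive scan.
6. **Classification.** The significant edges become classifier candidates.
   Features are ranked by a two-sample t-test on the full sample, then
   added one at a time in rank order; each feature-set size is scored by
   leave-one-out cross-validated (LOOCV) linear SVM accuracy, producing an
   accuracy-versus-k curve whose operating point is the smallest k
   attaining the maximum.

## Statistical choices worth stating

**Permutation p-values.** Monte-Carlo p-values use the `(b + 1)/(B + 1)`
estimator, which cannot return zero and is exactly valid under
exchangeability. When the number of distinct label assignments is at most
184,756 (e.g. 10 + 10), the test switches to exhaustive enumeration and the
p-value is exact. The t statistic is the pooled-variance Student form; under
permutation the test is valid regardless of that choice.

**No multiple-testing correction** is applied across the 6216 edges — the
threshold p < 0.01 uncorrected replicates the motivating protocol. At the
null this flags about 62 edges by chance; the package's calibration tests
verify the per-edge false-positive rate rather than pretending family-wise
control. `p.adjust` can be applied to the returned tibble by users who want
FDR.

**Circularity is measured, not hidden.** Ranking features on the full
sample before LOOCV (and, a fortiori, selecting candidates by full-sample
significance) lets the held-out subject influence feature choice. The
default protocol reproduces this faithfully because it is the protocol
being re-implemented; `selection_bias_audit()` quantifies the resulting
optimism by re-ranking features inside every training fold and comparing
curve accuracies. On pure-null features the non-nested protocol's maximum
scores far above chance while the nested curve's mean stays at 0.5 — a
property the test suite asserts. Note that even a nested curve's *maximum*
over k is optimistic on null data (choosing the best of `k_max` correlated
accuracy estimates is itself a selection step), which is why the audit
reports both the maximum and the mean of each curve.

**SVM configuration.** Kernel and regularisation are not dictated by the
protocol being reproduced; the defaults are a linear kernel with C = 1, the
standard small-n connectome choice, and features are standardised with
training-fold statistics only. Both are exposed in `classifier_config()`.

**Demographic table tests.** Group summaries are compared with two-sample
t-tests from summary statistics (pooled by default, Welch available) and a
Pearson chi-square without continuity correction for 2x2 gender counts.
Published cohort tables of this design sometimes print p-values that a
two-sample t on the printed summaries does not reproduce (e.g. an age
comparison printing p = 0.081 where the summaries give ~0.006); the package
reports what it computes and keeps printed values only as fixture columns
for comparison.

## The synthetic cohort generator

The generator's defaults are the study conditions: 21 + 23 participants,
112 ROIs, 420 volumes at TR 2 s, and a motion profile whose worst mover has
37 supra-threshold volumes so uniform trimming retains 379 volumes.

* **Group structure.** Both groups share one random correlation matrix
  (random orthogonal eigenvectors, gamma-normalised eigenvalues). Effect
  edges are offset symmetrically in Fisher-z space (±delta_z/2) and each
  matrix is projected back to the nearest correlation matrix (Higham
  alternating projections, tolerance 1e-8); the realised z-difference is
  checked against the request within ±0.05. The protocol reports only
  p-values for its significant edges, so the effect size in z-units is a
  generator calibration choice: the default five edges at |delta_z| = 0.8
  give near-certain per-edge detection at these group sizes, which is what
  a power property needs to be stable across seeds.
* **Sampling.** Each participant's latent series is multivariate normal
  with the group matrix. Observation noise (sd 0.2), a linear drift, WM and
  CSF sinusoidal source contamination and a standardised linear combination
  of that participant's own motion parameters are added on top. Every
  contaminant lies in the span of the preprocessing regressors (or the
  filter stop band), so the pipeline can remove them exactly and
  parameter-recovery tests exercise the whole chain rather than a lucky
  shortcut.
* **Motion.** Baseline parameters follow a slow clamped random walk
  (per-step sd 0.02 mm / 0.0002 rad) whose FD stays below 0.23 mm by
  construction; spikes are permanent single-volume translation jumps
  (default 1 mm), each producing exactly one supra-threshold FD volume, so
  spike counts are exact and auditable.
* **Scores.** The behavioural score is a linear transform of the
  participant's realised Fisher-z value at a designated edge plus Gaussian
  noise calibrated so the generative correlation equals `coupling_r`
  (default −0.511 in group A). The score edge also carries between-subject
  heterogeneity in its true connectivity (sd 0.3 z-units in both groups),
  injected as a shared rank-1 component so positive semi-definiteness is
  automatic. Without subject-level variation the only across-subject spread
  at an edge would be estimation noise and no finite scan length could
  recover an edge–score correlation; with it, full-pipeline runs recover
  correlations near the generative value.

**What the generator does not emulate:** hemodynamic response shape,
scanner drift beyond a linear term, spatial misregistration, physiological
aliasing structure, real between-subject network topology variation, or
site/session effects. Passing tests demonstrate that the statistical
machinery is correct under the stated generative model — not that any
particular real-data finding is right.

## Numerical choices

* **FD rotation radius** defaults to 50 mm (the common sphere convention);
  it is a parameter because source datasets vary.
* **Filter implementation.** Butterworth order 2 applied forward and
  backward (effective order 4, zero phase). `signal::filtfilt` does not use
  steady-state initial conditions, so the package demeans each series and
  applies odd-extension padding (up to 100 samples per side) before
  filtering; the pass band retains ≥ 99% amplitude at 0.05 Hz while DC is
  removed exactly and 0.2 Hz is attenuated below 1% (measured away from
  series edges — zero-phase filtering of a short window always leaves edge
  transients, which is why gain contracts are checked on long sinusoids).
* **Trimming ties.** When a participant needs extra removals beyond their
  flagged volumes, the highest-FD remaining volumes go first, ties broken
  by the later volume index; deterministic and tested by brute force.
* **PC sign.** The first principal component's sign is arbitrary; it is
  fixed by non-negative correlation with the ROI mean series.
* **Degenerate inputs.** Edges constant in both groups get t = 0, p = 1
  with a warning; perfectly correlated ROI pairs are representable as
  r = ±1 but refuse the Fisher transform; rank-deficient nuisance designs
  are an error naming the collinear columns.
* **Problem sizes in the test-suite.** Power properties run 50 seeded
  cohorts at full study size (21/23, 112 ROIs, 420→379 volumes) with 1,000
  permutation replicates (granularity 1/1001, ample for alpha = 0.01);
  null calibration uses 2,000 edges × 2,000 replicates; the selection-bias
  audit uses 20 seeds of 44 × 6216 null features. These sizes make the
  stochastic assertions stable while keeping a full run in minutes.

## Known limitations

* Censored (non-contiguous) series are bandpass-filtered as if contiguous,
  matching the common practice the pipeline reproduces; interpolation-based
  scrubbing is out of scope.
* The 112-region label table is a synthetic transcription: it covers the
  region names used by the bundled edge tables and pads to 112 bilateral
  labels; it fixes matrix ordering and nothing else.
* `summary_two_sample_t` works from printed summaries and cannot detect
  whatever covariate adjustment a source table may have silently used.
* The per-edge score-correlation scan is reported uncorrected by design;
  with 46 edges × 2 groups, ~2 spurious hits at p < 0.05 are expected.
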