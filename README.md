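# restconn

Group analysis of resting-state functional connectivity, from motion-aware
volume censoring to edge-wise permutation inference and connectome-based
classification — with a synthetic cohort generator that gives every stage a
known ground truth.

## The problem

Resting-state fMRI measures spontaneous low-frequency BOLD fluctuations;
the Pearson correlation between the time series of two brain regions (an
*edge* of the connectome) indexes their functional coupling. A classic
two-group design asks which edges differ between cohorts — for example
experts versus non-experts in some skill — and whether the multivariate
edge pattern identifies group membership. restconn implements that whole
chain for ROI-level data:

1. **Frame-wise displacement (FD)** per volume:
   `FD_t = Σ|Δd_i| + r·Σ|Δθ_j|` over the six rigid-body realignment
   parameters (rotations mapped to arc length on an `r = 50` mm sphere),
   with cohort-uniform censoring: after dropping the first four volumes,
   the worst mover's supra-threshold count (FD > 0.5 mm) fixes how many
   volumes every participant loses, so each subject contributes equally.
2. **Nuisance regression** (anatomical CompCor): OLS removal of the top 5
   white-matter and 5 CSF principal-component series, six linearly
   detrended motion parameters, intercept and trend.
3. **Zero-phase Butterworth bandpass**, 0.01–0.1 Hz.
4. **Connectivity**: first-PC representative series per ROI, all pairwise
   Pearson r over a 112-region parcellation, Fisher-transformed
   (`z = atanh r`) into 6216 edge features per subject.
5. **Edge-wise permutation t-tests** (pooled-variance t, label
   permutation, `p = (b+1)/(B+1)`, exact enumeration for small groups),
   significance filtering at p < 0.01 (uncorrected) with direction
   blocks, and per-group Pearson correlations between significant edges
   and a behavioural score.
6. **Classification**: t-ranked sequential feature addition over the
   significant edges, scored by leave-one-out cross-validated linear SVM
   accuracy (`accuracy_curve()`), plus `selection_bias_audit()`, which
   quantifies the optimism of ranking features on the full sample instead
   of inside each training fold.

The synthetic generator (`sim_config()` / `simulate_cohort()`) emits
two-group cohorts (defaults: 21 + 23 subjects, 420 volumes at TR 2 s)
with injected Fisher-z edge effects, motion spikes that trip the FD
threshold on demand, WM/CSF/motion contamination that the preprocessing
can provably remove, and scores coupled to a designated edge.

## Worked example

```r
library(restconn)

cfg <- sim_config(seed = 2024)       # 21 + 23 subjects, 5 injected edges
cohort <- simulate_cohort(cfg)
result <- run_pipeline(cohort, replicates = 1000, seed = 7)
result
#> <restconn_result>
#>   retained volumes: 379 (removed 37)
#>   significant edges: 59 (A > B: 32; B > A: 27)
#>   LOOCV accuracy: max 100.00% at k = 1
```

The worst mover in the default motion profile has 37 supra-threshold
volumes, so every subject keeps 379 of 420 volumes. At alpha = 0.01
uncorrected, roughly `0.01 × 6216 ≈ 62` edges are expected by chance on
top of the 5 injected ones; the injected edges sit at the permutation
floor (`p = 1/1001`) with the largest t statistics:

```r
head(filter_significant(result$edge_stats, 0.01), 3)
#> # A tibble: 3 × 8
#>    edge roi_i roi_j abbrev_i abbrev_j     t        p direction
#>   <int> <int> <int> <chr>    <chr>    <dbl>    <dbl> <chr>
#> 1   217     2   108 FP.R     VDc.R     25.3 0.000999 A > B
#> 2  1052    10    99 OpIFG.R  CN.L     25.2 0.000999 A > B
#> 3  1071    11    17 TrIFG.L  LOrG.L   32.1 0.000999 A > B
```

— three of the five injected effects. The generator couples the
behavioural score to the left–right caudate edge (CN.L–CN.R) at a
generative correlation of −0.511 in group A, and the full pipeline
recovers it:

```r
edge_score_correlation(result$features$z[groupA, caudate_edge],
                       result$features$participants$score[groupA])
#> # A tibble: 1 × 3
#>        r      p     n
#>    <dbl>  <dbl> <int>
#> 1 -0.510 0.0181    21
```

`autoplot(result$curve)` draws the accuracy-versus-features curve with
its operating point.

## Command line

A thin CLI over the same functions ships in `inst/cli/restconn`:

```sh
restconn simulate --out cohort_dir --seed 1
restconn run-all  --cohort cohort_dir --out results --replicates 10000
```
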