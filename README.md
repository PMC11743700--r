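# plstate

Dynamic functional-connectivity analysis of parcellated resting-state fMRI
by leading-eigenvector dynamics: detection of recurrent phase-locking (PL)
states, fractional-occupancy statistics between groups, cross-granularity
coupling modes, and covariate correlations — together with a synthetic
cohort generator that plants known states so every stage of the pipeline
can be validated against ground truth.

## The problem and the method

Static functional connectivity summarizes a whole scan with one correlation
matrix, discarding the fact that cortical networks form and dissolve on the
scale of seconds. The leading-eigenvector approach characterizes each fMRI
volume individually:

1. **Instantaneous phases.** Each parcel's BOLD series `x_n(t)` (N parcels
   × T volumes) is demeaned and transformed into its analytic signal via
   the Hilbert transform, giving a phase `θ_n(t)`. The first and last
   volumes are dropped (edge distortion), leaving T′ = T − 2.
2. **Dynamic phase coherence.** At each volume the N × N matrix
   `dPC_np(t) = cos(θ_n(t) − θ_p(t))` captures pairwise phase alignment:
   +1 in-phase, −1 anti-phase, 0 in quadrature.
3. **Leading eigenvectors.** The dominant eigenvector `V1(t)` of `dPC(t)`
   splits the cortex into two phase communities by the signs of its
   elements. Signs are canonicalized so the smaller (anti-phase) community
   is positive. `dPC` is exactly rank ≤ 2
   (`dPC = cos θ cos θᵀ + sin θ sin θᵀ`), which the implementation
   exploits to compute `V1` from a 2 × 2 eigenproblem.
4. **PL states.** All eigenvectors, pooled across scans, are clustered by
   k-means under cosine distance for k = 2…20. Each cluster centroid `Vc`
   is a PL state; the state whose centroid has no positive element is the
   *global mode* (whole cortex in phase). Each scan becomes a sequence of
   states, and each state's *probability of occurrence* (fractional
   occupancy) is its share of the scan's volumes.
5. **Statistics.** Group differences in occupancy are tested per state by
   a permutation test on the pooled-variance t statistic (10,000 label
   permutations), Bonferroni-tiered within each partition model
   (`p < 0.05/k`), with the biased Hedges' g
   (`g = |x̄₁ − x̄₂| / s*`, pooled SD `s*`) as effect size. Significant
   states from different k are grouped into *coupling modes* when their
   centroids correlate (r ≥ 0.8) and share the group-difference direction.
   Occupancies are correlated with subject covariates (age, meditation
   expertise, mysticism-scale scores) by Spearman's ρ with Holm–Bonferroni
   correction per partition model.

## Worked example

Simulate a 36-subject cohort (19 controls, 17 meditators, 90 parcels, 180
volumes at TR = 3 s) with three planted states and a planted occupancy
difference of 0.15 on state 2, then recover and test it:

```r
library(plstate)

lib <- list(
  planted_state(1L, rep(FALSE, 90), "global"),
  planted_state(2L, c(rep(TRUE, 22), rep(FALSE, 68)), "posterior"),
  planted_state(3L, c(rep(FALSE, 22), rep(TRUE, 22), rep(FALSE, 46)), "frontal"))
spec <- cohort_spec(
  n_parcels = 90, n_volumes = 180,
  group_sizes = c(control = 19L, meditator = 17L),
  state_library = lib,
  occupancy_by_group = list(control   = c(0.425, 0.20, 0.375),
                            meditator = c(0.350, 0.35, 0.300)),
  noise_sd = 0.1, covariate_links = NULL, seed = 42)
cohort <- generate_cohort(spec)

pool <- pool_eigenvectors(lapply(cohort$scans, eigenvector_series))
print(pool)
#> Pooled eigenvectors: 6408 volumes from 36 scans, 90 parcels

model <- cluster_partition(pool, k = 3, seed = 1, replicates = 10)
print(model)
#> Partition model k = 3 ( 6408 volumes )
#>   cluster sizes: 2457, 2205, 1746
#>   global mode: 1

occ <- occurrence_table(model)
res <- compare_groups(list(k3 = occ), cohort$metadata, M = 10000, seed = 1)
res[, c("k", "cluster", "p_value", "tier", "direction", "g", "mean_1", "mean_2")]
#>   k cluster p_value      tier direction     g mean_1 mean_2
#> 1 3       1  0.0301   nominal   control 0.754  0.433  0.328
#> 2 3       2  0.8722        ns meditator    NA  0.341  0.348
#> 3 3       3  0.0083 corrected meditator 0.945  0.226  0.325
```

Cluster 1 is flagged as the global mode and is the most occupied state.
Cluster 3 recovers the planted posterior state: meditators occupy it more
(`mean` 0.325 vs 0.226, matching this cohort's realized ground truth of
0.325 vs 0.220), the permutation p = 0.0083 survives the per-partition
Bonferroni threshold 0.05/3, and Hedges' g ≈ 0.95. `mean_1`/`mean_2` are
the control/meditator group means of fractional occupancy.

The full sweep (k = 2…20, coupling modes, covariate correlations, TSV
reports and a JSON run manifest) is one call:

```r
cfg <- run_config(simulation = spec, k_min = 2, k_max = 20,
                  permutations = 10000, seed = 1)
run_pipeline(cfg, "out/")
```

or, from a shell, `exec/plstate simulate|run|report` with a YAML config.

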