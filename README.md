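# nethom

Voxel-wise **network homogeneity (NH)** analysis of resting-state fMRI,
for researchers studying the coherence of large-scale brain networks —
typically the default-mode network (DMN) — in case-control designs.

For every voxel *i* inside a binary network mask of *N* voxels, NH is the
mean Pearson correlation of that voxel's time series with every other
in-mask series:

```
NH(i) = (1 / (N-1)) * sum_{j != i} corr(x_i, x_j)
```

A voxel with low NH is discoordinated from the rest of its network; a
case-control difference in NH localizes where a network's internal
coherence changes with disease. The package implements the full analysis
around this statistic:

* **Synthetic cohorts** (`sim_spec()`, `generate_cohort()`): seeded
  two-group BOLD simulations with a known network mask, planted regional
  coupling increases/decreases in patients, AR(1) motion traces with
  calibratable framewise displacement, and phenotype variables planted to
  correlate with regional NH. The generator's coupling model has
  closed-form true correlations, so every downstream stage can be tested
  against analytic oracles.
* **Temporal preprocessing and motion QC** (`preprocess_run()`,
  `compute_framewise_displacement()`, `apply_exclusion_rule()`): volume
  dropping, nuisance regression, 0.01–0.08 Hz band-pass, Power FD, and
  the 2 mm / 2° / mean-FD 0.5 mm exclusion rule.
* **Network mask by group ICA** (`derive_network_mask()`): PCA reduction
  of concatenated control runs, fixed-point spatial ICA with restarts,
  template-matched component selection, threshold + cluster-filter
  binarization. Controls only — patients never influence the mask.
* **NH maps** (`compute_nh_map()`): O(N·T) computation with a brute-force
  pairwise oracle (`nh_bruteforce_oracle()`) for verification.
* **Group inference** (`cluster_extent_inference()`): voxel-wise GLM of
  NH on group with age and mean-FD covariates, cluster-forming threshold
  p < 0.001, and cluster-level family-wise error control by a
  label-permutation max-cluster-extent null, Bonferroni-corrected across
  the two signed contrasts. Reports peak coordinates in mm, extent, peak
  t and FWE p per cluster.
* **Clinical correlation** (`correlate_regions_with_clinical()`):
  Pearson r with exact t-based p-values between cluster-mean NH and
  clinical variables (lipids, RBANS cognitive scores, …) within the
  patient group, pairwise-complete.
* **Classification** (`loo_svm_single_region()`): patient-vs-control
  RBF-SVM (LIBSVM via e1071) on one region's NH under leave-one-out
  cross-validation with grid-searched C and gamma; sensitivity,
  specificity and accuracy with confusion counts.
* **Pipeline** (`run_pipeline()`): YAML-configured end-to-end driver
  writing NIfTI volumes, TSV tables and a bit-reproducible JSON
  manifest. A thin CLI lives at `inst/cli/nethom.R`.

See the vignette (`vignettes/network-homogeneity-methods.Rmd`) for the
model, all tunable parameters, and design rationale.

## Worked example

Simulate a default cohort (20 patients + 20 controls, 18×22×18 grid, 100
volumes at TR 2 s, coupling +0.40 planted in the "mpfc" box and −0.30 in
the "pcc" box of patients), preprocess, compute NH, and run the group
comparison with 500 permutations:

```r
library(nethom)

co   <- generate_cohort(sim_spec(seed = 1))
fds  <- sapply(co$motions, function(m) compute_framewise_displacement(m)$mean_fd)
runs <- lapply(seq_along(co$runs), function(i)
  preprocess_run(co$runs[[i]], co$motions[[i]])$run)
nh   <- lapply(runs, compute_nh_map, mask = co$mask_truth)

design   <- group_design(co$phenotypes$subject_id, co$phenotypes$group,
                         co$phenotypes$age, fds)
clusters <- cluster_extent_inference(nh, design, n_perm = 500, seed = 1)
as.data.frame(clusters)
#>     cluster         direction peak_x_mm peak_y_mm peak_z_mm extent peak_t
#> 1 cluster01 patients>controls         6        30        18    124  8.785
#> 2 cluster02 patients<controls        -2       -26        -2     80 -7.191
#>      fwe_p
#> 1 0.003992
#> 2 0.003992
```

Both planted effects are recovered: one cluster where patients exceed
controls (124 of the 125 planted "mpfc" voxels, peak t = 8.8) and one
where they fall below (80 of 125 planted "pcc" voxels, peak t = −7.2),
each at the minimal attainable permutation FWE p = 2 × 1/501 ≈ 0.004 and
nothing elsewhere. Cluster-mean NH then feeds the clinical and
classification stages:

```r
features <- extract_region_means(nh, clusters)
correlate_regions_with_clinical(features, co$phenotypes, c("TG", "HDL_C"))
#>      region variable  n       r     p
#> 1 cluster01       TG 20  0.0291 0.903
#> 2 cluster01    HDL_C 20 -0.2009 0.396
#> 3 cluster02       TG 20 -0.2791 0.233
#> 4 cluster02    HDL_C 20 -0.3539 0.126

classify_all_regions(features, co$phenotypes$group)[,
  c("region", "sensitivity", "specificity", "accuracy")]
#>      region sensitivity specificity accuracy
#> 1 cluster01          95         100     97.5
#> 2 cluster02         100         100    100.0
```

The correlations illustrate measurement attenuation: phenotypes are
planted against the *true* regional NH (HDL-C at r = −0.34 against the
pcc region), and estimates from measured 20-patient region means are
noisier and biased toward zero — here r = −0.35 for the pcc cluster but
not significant at n = 20. The near-perfect classification reflects the
deliberately strong planted effects. The same analysis runs end-to-end
with `run_pipeline(default_config(), "out/")`, which also writes the QC
report, all tables, and a manifest whose checksums are identical across
reruns with the same config and seed.

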