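---
title: "Network homogeneity analysis: model, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network homogeneity analysis: model, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nethom)
```

## The statistic

Network homogeneity (NH) asks, for every voxel inside a network mask, how
coherent that voxel is with the rest of the network. For in-mask voxels
$i = 1, \dots, N$ with time series $x_i$,

$$\mathrm{NH}(i) = \frac{1}{N-1}\sum_{j \neq i} \mathrm{corr}(x_i, x_j).$$

`compute_nh_map()` evaluates this with the standardized-sum identity:
after z-scoring every series (sample SD, denominator $T-1$), the row sum
$q = \sum_j z_j$ satisfies $\sum_j \mathrm{corr}(x_i,x_j) = z_i^\top q /
(T-1)$, so a full map costs $O(NT)$ rather than $O(N^2 T)$. The explicit
pairwise matrix lives on as `nh_bruteforce_oracle()`, kept solely so the
two routes can be compared to $10^{-10}$ in the test suite. Raw
correlations are averaged, not Fisher-z transformed, matching the plain
definition of the statistic; a Fisher-z mode could be added behind the
same interface if a study required it.

The analysis pipeline around the statistic follows the case-control
design common in resting-state psychiatry studies: temporal
preprocessing with motion quality control, a group-ICA-derived network
mask computed from controls only, per-subject NH maps, voxel-wise group
inference with permutation cluster-level FWE correction and age/mean-FD
covariates, Pearson correlation of cluster-mean NH with clinical
variables within the patient group, and single-region RBF-SVM
classification under leave-one-out cross-validation.

## The synthetic cohort model

No public dataset accompanies this class of study, so the package's
cohorts are simulated by `generate_cohort()` from an explicit
generative model. Every in-network voxel belonging to region $R$ of
subject $s$ is

$$x_v = \sigma\left(\sqrt{w_{sR}}\, L_s + \sqrt{1-w_{sR}}\,
\varepsilon_v\right),$$

where $L_s$ is a subject-level latent signal, $\varepsilon_v$ is
voxel-specific noise, and $w_{sR} \in (0,1)$ is the coupling weight. Two
voxels in regions with weights $w_1, w_2$ then have true correlation
$\sqrt{w_1 w_2}$ — equal to $w$ within one region — which yields
closed-form expected NH values (`true_region_nh` internally) used as
analytic oracles throughout the tests.

Both $L_s$ and $\varepsilon_v$ are random-phase sinusoid mixtures
supported exactly on the 0.01–0.08 Hz band that the preprocessing
retains. Band-limiting the *noise* as well as the latent is deliberate:
band-passing white noise would discard roughly 72 % of its variance and
silently inflate every sample correlation (a weight of 0.4 would appear
as ≈ 0.70 after filtering), compressing planted increases against the
ceiling at $r = 1$. With matched supports, temporal preprocessing leaves
the correlation structure invariant and the closed-form oracles remain
valid end to end.

Key generator defaults, all overridable through `sim_spec()`:

* **Grid and timing** — 18×22×18 voxels at 4 mm, 100 volumes, TR 2 s,
  20 patients + 20 controls. This desk scale keeps the full pipeline,
  including permutation inference, within minutes on one CPU while
  preserving the 2 s repetition time typical of the acquisitions being
  emulated (clinical cohorts of ~40 per arm, 250 volumes).
* **Network** — four disjoint 125-voxel boxes labeled after default-mode
  constituents (mpfc, pcc, precuneus, ltc), 500 voxels in total.
* **Coupling** — base weight $w = 0.4$, between-subject SD 0.03 (this
  jitter gives regional NH its across-subject variance, which carries
  the planted phenotype correlations).
* **Planted effects** — patients' coupling shifted by +0.40 in the mpfc
  box and −0.30 in the pcc box. The emulated studies publish no usable
  effect size, so the deltas are free parameters; they were fixed once
  so that planted clusters are recovered reliably at this temporal
  resolution. With 90 retained volumes of 0.07 Hz-wide signal a run
  carries only ≈ 26 effective temporal degrees of freedom, so
  correlation estimates are noisy and weak deltas produce erratic
  voxel-level detection; the chosen values give peak $|t| \approx$ 7–10
  at $n = 40$, on the high side of, but comparable to, reported NH
  case-control differences.
* **Motion** — six rigid-body series simulated as mean-reverting AR(1)
  random walks ($\rho = 0.95$), translations in mm and rotations scaled
  by a 50 mm head radius so both contribute equally to framewise
  displacement. Mean reversion (rather than a pure random walk) keeps
  low-motion subjects from drifting across the 2 mm exclusion threshold
  by chance over long runs, and the stationary increments give the
  closed-form calibration `motion_scale_for_fd()` (expected FD per frame
  $= 6\,s\sqrt{2/(1+\rho)}\sqrt{2/\pi}$). Patients target a mean FD of
  0.15 mm, controls 0.10 mm; `n_high_motion` plants subjects above the
  0.5 mm exclusion cap to exercise the QC rule.
* **Phenotypes** — each planned variable is $\mu + \sigma(r z +
  \sqrt{1-r^2}\epsilon)$ with $z$ the standardized *true* regional NH
  across patients, so the planted $r$ is the population correlation.
  One variable targets one region; the default plan mirrors magnitudes
  around |r| ≈ 0.34–0.44 for lipids and RBANS verbal scores. Unplanned
  variables are independent of NH. An optional missing-at-random
  fraction exercises pairwise-complete handling.
* **Motion confound** — `fd_confound` adds coupling proportional to a
  subject's realized mean FD, creating an NH–motion artifact used to
  demonstrate that the mean-FD covariate restores nominal false-positive
  control.

What the generator does *not* emulate: spatially smooth anatomy-driven
NH profiles, physiological (cardiac/respiratory) noise, susceptibility
artifacts, misregistration, or tissue compartments for WM/CSF nuisance
signals. Passing tests therefore demonstrate the pipeline's statistical
behavior under a known coupling model, not robustness to every artifact
of real acquisitions.

## Preprocessing

The temporal chain is fixed and logged: drop initial volumes (default
10), regress nuisance signals (intercept + 6 motion parameters; a
Friston-24 expansion is available), band-pass 0.01–0.08 Hz by Fourier
masking. Spatial steps (realignment, normalization, smoothing) are out
of scope because synthetic data are generated on a common grid. Motion
QC excludes a subject when any cumulative translation exceeds 2 mm, any
rotation 2°, or mean Power FD 0.5 mm — the classic rule of the era being
emulated; every threshold is an argument. Global/WM/CSF regressors are
omitted because the synthetic data have no tissue compartments.

## Mask derivation

`derive_network_mask()` concatenates control runs (voxel series z-scored
within subject), reduces to `pca_k` principal components, and runs
fixed-point spatial ICA (tanh contrast, symmetric decorrelation, max
1000 iterations, tolerance $10^{-6}$), selecting the component whose
absolute z-map best correlates with a template and binarizing at z ≥ 2.3
with 26-connectivity cluster filtering (≥ 10 voxels). Controls-only
derivation mirrors the emulated design: the network definition must not
be influenced by patients.

Two behaviors differ from a textbook FastICA and are deliberate. First,
when the reduced data contain a spatially Gaussian minor subspace — the
synthetic case exactly: one strongly non-Gaussian network source plus
noise — the symmetric fixed-point rotation has no fixed point in that
subspace and cycles indefinitely while the network component stabilizes
within ~100 iterations. Hitting `max_iter` therefore raises a warning
(carrying the iteration count and final delta) and returns the estimate
instead of failing; divergence still errors. Second, the algorithm
restarts from up to 5 random initializations and keeps the run whose
best component has the largest log-cosh negentropy: occasionally an
initialization fails to isolate the network source, and the most
non-Gaussian decomposition is a template-independent criterion for
choosing among restarts. A decisively non-Gaussian component (negentropy
proxy above $10^{-3}$, two orders of magnitude above anything Gaussian
maps attain at these sizes) ends the search early.

## Group inference

Per voxel, NH is regressed on intercept, group (patient = 1, so
positive $t$ means patients > controls), age, and mean FD. Candidate
clusters form at two-tailed voxel $p < 0.001$ (26-connectivity), and
cluster-level FWE control comes from the permutation null of the maximum
cluster extent: group labels are permuted (covariates stay with their
subjects), the GLM is refit, and the maximum supra-threshold extent
across both signs is recorded. Cluster $p = (1 + \#\{\text{perm max}
\geq \text{observed}\})/(1 + n_{\text{perm}})$, Bonferroni-doubled
across the two signed contrasts — the most defensible reading of a
cluster-level Bonferroni combined with FWE, exposed as a flag. A
permutation null was chosen over Gaussian-random-field theory because it
is exact at desk scale on small grids without smoothness estimation.
Peaks are the maximum-|t| voxel (ties to the lowest linear index),
reported in world mm through the affine (0-based voxel convention),
rounded to one decimal.

Per-subject mask-wise z-standardization of NH maps before group
statistics (`standardize_nh_map()`) is provided but **off by default**.
On cohorts whose true NH profile is spatially flat — the synthetic
model, where all four regions share one baseline weight — the control
maps' in-mask SD is almost entirely measurement noise, so z-scoring
amplifies idiosyncratic noise to unit scale and saturates planted-effect
amplitudes (in calibration runs the voxel-level $t$ plateaued near 5
regardless of the planted delta). Raw NH comparison preserves power and
keeps the analytic oracles interpretable. On real data with strong
shared spatial structure the flag may be worth enabling; that is a
data-analytic choice, not a property of the statistic.

## Clinical correlation and classification

Correlations are plain Pearson $r$ with the exact $t$-based two-sided
p-value, computed within the patient group, pairwise-complete, with the
effective $n$ recorded per test; no multiple-testing adjustment is
applied by default (mirroring how such tables are usually reported), and
Benjamini–Hochberg is available behind a flag. Note an attenuation
effect that the tests make explicit: phenotypes are planted against the
*true* model-implied regional NH, so correlations estimated from
*measured* region means are biased toward zero by measurement noise —
at desk scale roughly a factor of two. The recovery contract (mean
estimated $r$ within ±0.05 of the planted value over 50 cohorts) is
therefore stated against the true regional NH, while the measured-NH
path is tested against its wider sampling band. Real studies face the
same attenuation; published $r$ values understate latent coupling.

Classification uses a Gaussian-kernel soft-margin SVM (LIBSVM via
e1071) on one region's mean NH, leave-one-out cross-validated, features
z-scored with training-fold statistics inside each iteration to prevent
leakage. Hyperparameters $C, \gamma \in \{2^{-5}, 2^{-3}, \dots,
2^{5}\}$ are selected by maximal LOO accuracy with ties resolved to the
smallest $C$ then $\gamma$. Selecting on the same LOO loop is
optimistic — on label-permuted nulls at $n = 40$ the mean reported
accuracy sits near 58 % rather than 50 % — which is documented rather
than hidden because it mirrors how such tables are produced in the
emulated literature; `nested = TRUE` provides honest nested-CV estimates
at ~40× the cost. Patients are the positive class throughout.

## Numerical and formatting conventions

Permutation p-values use the add-one estimator and are therefore never
zero. NH values are clipped to $[-1, 1]$ only against floating-point
overshoot. Zero-variance voxel series are hard errors naming the voxel,
never silent zeros, because they indicate an upstream fault. Volumes
are written as uncompressed 32-bit-float NIfTI-1 (gzip headers embed a
timestamp, which would break bit-identical reproduction); tables are TSV
with 6-significant-digit floats; manifests are JSON containing the
config hash and per-file md5 checksums but no wall-clock timestamps, so
`run_pipeline()` with a fixed config and seed is bit-reproducible.
Wall-clock times go to `pipeline.log`.

## Problem sizes used by the test suite

The suite regenerates everything from code: oracle equivalence on 100
random run/mask pairs (T = 60, ≤ 200 voxels); the analytic coupling
limit at T = 2000; planted-effect recovery on 10 default cohorts with
500 permutations each; FWE calibration on 100 null cohorts (10×10×10
grid, 12+12 subjects, 200 permutations) with and without a planted
motion confound; correlation recovery over 50 cohorts at $n = 40$
patients; and the classification regimes at $n = 40$. These sizes were
chosen so the whole suite completes in minutes on a single CPU while
leaving each statistical bound clear margin.

## Known limitations

* The coupling model induces cross-region correlations
  $\sqrt{w_A w_B}$, so a planted change in one region shifts other
  regions' NH slightly (second-order spillover); the permutation null
  absorbs it at default effect sizes.
* Group ICA on rank-one synthetic networks recovers the mask
  essentially perfectly (Dice 1.0), which says nothing about component
  splitting on real hierarchical networks.
* The LOO hyperparameter-selection optimism above means reported
  accuracies are upper-ish estimates by construction, as in the
  emulated analyses.
* Single-feature classification only; no multi-voxel or whole-map
  decoding.
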