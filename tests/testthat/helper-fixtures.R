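# Shared fixtures: small cohorts and runs built in code at test time.

# two-region 10x10x10 spec, fast to generate
tiny_spec <- function(seed = 1L, n_patients = 12L, n_controls = 12L,
                      n_volumes = 60L, effect_regions = list(),
                      phenotype_plan = list(), ...) {
  sim_spec(grid_shape = c(10L, 10L, 10L), n_volumes = n_volumes,
           n_patients = n_patients, n_controls = n_controls,
           network_regions = list(
             list(label = "a", x = c(2, 5), y = c(2, 5), z = c(2, 5)),
             list(label = "b", x = c(6, 9), y = c(6, 9), z = c(6, 9))),
           effect_regions = effect_regions,
           phenotype_plan = phenotype_plan, seed = seed, ...)
}

# iid-noise run on a small grid (no network structure)
random_run <- function(seed, grid = c(6L, 6L, 6L), nt = 60L, tr_s = 2) {
  withr::with_seed(seed,
    bold_run(array(rnorm(prod(grid) * nt), c(grid, nt)), tr_s = tr_s,
             subject_id = sprintf("rand-%d", seed)))
}

# mask of the first n voxels of a grid
first_voxels_mask <- function(grid, n, affine = diag(4)) {
  ind <- array(FALSE, grid)
  ind[seq_len(n)] <- TRUE
  network_mask(ind, affine)
}

# NH maps + design from a generated cohort, no preprocessing
cohort_nh <- function(cohort, standardize = FALSE) {
  nh <- lapply(cohort$runs, compute_nh_map, mask = cohort$mask_truth)
  if (standardize) nh <- lapply(nh, standardize_nh_map)
  design <- group_design(cohort$phenotypes$subject_id,
                         cohort$phenotypes$group,
                         cohort$phenotypes$age,
                         cohort$truth$true_mean_fd)
  list(nh = nh, design = design)
}
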