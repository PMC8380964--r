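make_maps <- function(Y, mask) {
  # wrap a subjects x voxels matrix as nh_map objects
  idx <- which(mask$indicator)
  lapply(seq_len(nrow(Y)), function(i) {
    vals <- array(NA_real_, dim(mask$indicator))
    vals[idx] <- Y[i, ]
    structure(list(values = vals, mask = mask, standardized = FALSE,
                   subject_id = sprintf("s%02d", i)),
              class = "nh_map")
  })
}

test_that("the covariate-free voxel t equals the two-sample t oracle", {
  grid <- c(4L, 4L, 2L)
  mask <- first_voxels_mask(grid, 20)
  n <- 14L
  Y <- withr::with_seed(3, matrix(rnorm(n * 20), n, 20))
  grp <- rep(c("patient", "control"), each = 7)
  des <- group_design(sprintf("s%02d", 1:n), grp, rep(30, n), rep(0.1, n))
  tm <- fit_voxelwise_glm(make_maps(Y, mask), des, use_covariates = FALSE)
  expect_equal(tm$df, n - 2L)
  idx <- which(mask$indicator)
  for (v in c(1, 7, 20)) {
    tt <- t.test(Y[grp == "patient", v], Y[grp == "control", v],
                 var.equal = TRUE)
    expect_equal(tm$t[idx[v]], unname(tt$statistic), tolerance = 1e-10)
  }
})

test_that("sign convention: planted patient increase gives positive t", {
  grid <- c(4L, 4L, 2L)
  mask <- first_voxels_mask(grid, 10)
  n <- 16L
  Y <- withr::with_seed(4, matrix(rnorm(n * 10, sd = 0.01), n, 10))
  Y[1:8, 3] <- Y[1:8, 3] + 1            # patients shifted up at voxel 3
  grp <- rep(c("patient", "control"), each = 8)
  des <- group_design(sprintf("s%02d", 1:n), grp,
                      withr::with_seed(5, runif(n, 20, 40)),
                      withr::with_seed(6, runif(n, 0, 0.3)))
  tm <- fit_voxelwise_glm(make_maps(Y, mask), des)
  idx <- which(mask$indicator)
  expect_gt(tm$t[idx[3]], 50)
  expect_lt(max(abs(tm$t[idx[-3]])), 6)
})

test_that("permutation p-values follow the add-one formula", {
  expect_equal(permutation_pvalue(0, 199), 1 / 200)
  expect_equal(permutation_pvalue(10, 199), 11 / 200)
  expect_equal(permutation_pvalue(199, 199), 1)
})

test_that("cluster inference finds a planted cluster and is deterministic", {
  co <- generate_cohort(tiny_spec(
    seed = 17, effect_regions = list(list(label = "a", sign = 1,
                                          delta = 0.4))))
  cn <- cohort_nh(co)
  cl <- cluster_extent_inference(cn$nh, cn$design, n_perm = 200L,
                                 seed = 31)
  expect_gte(nrow(cl), 1L)
  expect_equal(cl$direction[1], "patients>controls")
  expect_gt(cl$peak_t[1], 0)
  truth <- co$truth$region_labels == 1L
  lab <- attr(cl, "cluster_labels")
  got <- array(lab > 0, dim(lab))
  expect_gte(dice_coefficient(got, truth), 0.5)
  # peak coordinate lies inside the cluster (voxel -> mm via the affine)
  aff <- co$mask_truth$affine
  pk_vox <- round(solve(aff) %*% c(cl$peak_x_mm[1], cl$peak_y_mm[1],
                                   cl$peak_z_mm[1], 1))[1:3] + 1
  expect_true(lab[pk_vox[1], pk_vox[2], pk_vox[3]] != 0)

  cl2 <- cluster_extent_inference(cn$nh, cn$design, n_perm = 200L,
                                  seed = 31)
  expect_identical(as.data.frame(cl), as.data.frame(cl2))
  expect_identical(attr(cl, "null_max_extent"),
                   attr(cl2, "null_max_extent"))
})

test_that("null distributions are exchangeable with no effect", {
  co <- generate_cohort(tiny_spec(seed = 23))
  cn <- cohort_nh(co)
  tm <- fit_voxelwise_glm(cn$nh, cn$design)
  # max |t| stays below an extreme null bound for 128 voxels
  expect_lt(max(abs(tm$t), na.rm = TRUE),
            qt(1 - 0.0005 / 128, tm$df) + 2)
})

test_that("region means match a direct summation oracle", {
  co <- generate_cohort(tiny_spec(
    seed = 19, effect_regions = list(list(label = "b", sign = -1,
                                          delta = 0.35))))
  cn <- cohort_nh(co)
  cl <- cluster_extent_inference(cn$nh, cn$design, n_perm = 150L,
                                 seed = 7)
  expect_gte(nrow(cl), 1L)
  feats <- extract_region_means(cn$nh, cl)
  expect_equal(nrow(feats), length(cn$nh))
  lab <- attr(cl, "cluster_labels")
  cidx <- which(abs(lab) == 1L)
  oracle <- vapply(cn$nh, function(m) mean(m$values[cidx]), numeric(1))
  expect_equal(feats[[cl$cluster[1]]], oracle, tolerance = 1e-12)

  # uniform map -> region mean equals the constant
  flat <- cn$nh
  for (i in seq_along(flat))
    flat[[i]]$values[which(co$mask_truth$indicator)] <- 0.42
  f2 <- extract_region_means(flat, cl)
  expect_true(all(abs(as.matrix(f2[, -1]) - 0.42) < 1e-12))
})

test_that("design validation rejects malformed inputs", {
  expect_error(group_design("a", "patient", 30, 0.1), "non-empty")
  expect_error(group_design(c("a", "b"), c("patient", "control"),
                            c(30, NA), c(0.1, 0.1)), "finite")
  co <- generate_cohort(tiny_spec(seed = 2, n_patients = 4L,
                                  n_controls = 4L, n_volumes = 20L))
  cn <- cohort_nh(co)
  expect_error(cluster_extent_inference(cn$nh, cn$design, n_perm = 10L),
               "at least 100")
  expect_error(cluster_extent_inference(cn$nh, cn$design, voxel_p = 2,
                                        n_perm = 200L), "voxel_p")
})
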