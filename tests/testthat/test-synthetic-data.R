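test_that("a cohort is a pure function of its spec", {
  spec <- tiny_spec(seed = 11, n_volumes = 40L)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$runs[[1]]$data, b$runs[[1]]$data)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$motions[[5]]$params, b$motions[[5]]$params)
  expect_identical(a$truth$true_region_nh, b$truth$true_region_nh)
})

test_that("zero coupling delta leaves group-mean true NH equal", {
  co <- generate_cohort(tiny_spec(seed = 3, subject_coupling_sd = 1e-9))
  grp <- co$phenotypes$group
  nh <- co$truth$true_region_nh
  expect_equal(colMeans(nh[grp == "patient", ]),
               colMeans(nh[grp == "control", ]), tolerance = 1e-6)
})

test_that("a positive delta raises patient regional NH in nearly all replicates", {
  diffs <- vapply(1:50, function(s) {
    co <- generate_cohort(tiny_spec(
      seed = s, n_patients = 6L, n_controls = 6L, n_volumes = 20L,
      effect_regions = list(list(label = "a", sign = +1, delta = 0.2))))
    grp <- co$phenotypes$group
    nh <- co$truth$true_region_nh
    mean(nh[grp == "patient", "a"]) - mean(nh[grp == "control", "a"])
  }, numeric(1))
  expect_gte(mean(diffs > 0), 0.95)
})

test_that("true regional NH difference grows with the coupling delta", {
  mean_diff <- function(delta) {
    mean(vapply(1:20, function(s) {
      co <- generate_cohort(tiny_spec(
        seed = s, n_patients = 6L, n_controls = 6L, n_volumes = 20L,
        effect_regions = list(list(label = "a", sign = 1, delta = delta))))
      grp <- co$phenotypes$group
      nh <- co$truth$true_region_nh
      mean(nh[grp == "patient", "a"]) - mean(nh[grp == "control", "a"])
    }, numeric(1)))
  }
  d <- vapply(c(0.05, 0.15, 0.3), mean_diff, numeric(1))
  expect_true(all(diff(d) > 0))
})

test_that("degenerate and conflicting specs are rejected", {
  expect_error(tiny_spec(noise_sd = 0), "noise_sd")
  expect_error(sim_spec(effect_regions = list(
    list(label = "mpfc", sign = 1, delta = 0.1),
    list(label = "mpfc", sign = -1, delta = 0.1))), "conflicting signs")
  expect_error(tiny_spec(phenotype_plan = list(
    list(variable = "TG", region = "a", r = 1))), "\\(-1, 1\\)")
  expect_error(sim_spec(network_regions = list(
    list(label = "far", x = c(1, 99), y = c(1, 2), z = c(1, 2)))),
    "outside the grid")
  # spatially overlapping boxes with opposite effect signs
  expect_error(sim_spec(
    network_regions = list(
      list(label = "p", x = c(1, 4), y = c(1, 4), z = c(1, 4)),
      list(label = "q", x = c(3, 6), y = c(3, 6), z = c(3, 6))),
    effect_regions = list(list(label = "p", sign = 1, delta = 0.1),
                          list(label = "q", sign = -1, delta = 0.1))),
    "overlap")
})

test_that("motion traces scale linearly and vanish at scale zero", {
  z <- generate_motion_trace(50, 0, seed = 4)
  expect_true(all(z$params == 0))
  expect_equal(compute_framewise_displacement(z)$mean_fd, 0)
  m1 <- generate_motion_trace(50, 0.05, seed = 4)
  m2 <- generate_motion_trace(50, 0.10, seed = 4)
  fd1 <- compute_framewise_displacement(m1)$mean_fd
  fd2 <- compute_framewise_displacement(m2)$mean_fd
  expect_gt(fd2, fd1)
  expect_equal(fd2, 2 * fd1, tolerance = 1e-12)
  expect_error(generate_motion_trace(50, -1, seed = 1), "non-negative")
})

test_that("the FD calibration hits its target within 20 percent", {
  for (target in c(0.1, 0.3)) {
    sc <- motion_scale_for_fd(target, 100)
    got <- mean(vapply(1:20, function(s)
      compute_framewise_displacement(
        generate_motion_trace(100, sc, seed = s))$mean_fd, numeric(1)))
    expect_lt(abs(got - target) / target, 0.2)
  }
})

test_that("planted phenotype correlations are recovered against true NH", {
  # r = 0.5 at n = 40: mean sample correlation within 0.05
  plan <- list(list(variable = "TG", region = "a", r = 0.5))
  rs <- vapply(1:50, function(s) {
    spec <- tiny_spec(seed = s, n_patients = 40L, n_controls = 4L,
                      n_volumes = 20L, phenotype_plan = plan)
    co <- generate_cohort(spec)
    pat <- co$phenotypes$group == "patient"
    cor(co$phenotypes$TG[pat], co$truth$true_region_nh[pat, "a"])
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.5), 0.05)

  # r = 0.99 is nearly deterministic
  spec <- tiny_spec(seed = 1, n_patients = 40L, n_controls = 4L,
                    n_volumes = 20L,
                    phenotype_plan = list(
                      list(variable = "CHOL", region = "b", r = 0.99)))
  co <- generate_cohort(spec)
  pat <- co$phenotypes$group == "patient"
  expect_gt(cor(co$phenotypes$CHOL[pat],
                co$truth$true_region_nh[pat, "b"]), 0.9)

  # r = 0 stays near zero on average
  rs0 <- vapply(1:50, function(s) {
    spec <- tiny_spec(seed = s, n_patients = 40L, n_controls = 4L,
                      n_volumes = 20L,
                      phenotype_plan = list(
                        list(variable = "TG", region = "a", r = 0)))
    co <- generate_cohort(spec)
    pat <- co$phenotypes$group == "patient"
    cor(co$phenotypes$TG[pat], co$truth$true_region_nh[pat, "a"])
  }, numeric(1))
  expect_lt(abs(mean(rs0)), 2 / sqrt(40))
})

test_that("unplanned variables are independent of regional NH", {
  ps <- vapply(1:40, function(s) {
    spec <- tiny_spec(seed = s, n_patients = 20L, n_controls = 4L,
                      n_volumes = 20L)
    co <- generate_cohort(spec)
    pat <- co$phenotypes$group == "patient"
    pearson_with_pvalue(co$phenotypes$RBANS_total[pat],
                        co$truth$true_region_nh[pat, "a"])$p
  }, numeric(1))
  expect_lte(sum(ps < 0.05), 7)  # Bin(40, 0.05) upper 99.9% bound
})

test_that("effect masks and in-network voxels are consistent", {
  co <- generate_cohort(tiny_spec(
    seed = 2, effect_regions = list(list(label = "b", sign = -1,
                                         delta = 0.2))))
  em <- co$truth$effect_masks[["b"]]
  expect_true(all(em[em != 0] == -1))
  expect_true(all(co$mask_truth$indicator[em != 0]))
})
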