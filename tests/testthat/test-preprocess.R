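test_that("dropping initial volumes shifts the series and guards bounds", {
  run <- random_run(1, nt = 100L)
  expect_identical(drop_initial_volumes(run, 0), run)
  out <- drop_initial_volumes(run, 10)
  expect_equal(n_volumes(out), 90L)
  expect_equal(out$data[, , , 1], run$data[, , , 11])
  expect_error(drop_initial_volumes(run, 100L - 19L), "fewer than 20")
})

test_that("framewise displacement follows the Power formula", {
  p <- matrix(0, 10, 6)
  fd <- compute_framewise_displacement(motion_trace(p))
  expect_equal(fd$fd, rep(0, 10))
  expect_equal(fd$mean_fd, 0)

  p[5:10, 1] <- 0.1                       # one 0.1 mm step in x at frame 5
  fd <- compute_framewise_displacement(motion_trace(p))
  expect_equal(fd$fd[5], 0.1)
  expect_equal(sum(fd$fd), 0.1)

  p2 <- matrix(0, 10, 6)
  p2[3:10, 5] <- 0.01                     # 0.01 rad pitch step, 50 mm radius
  fd2 <- compute_framewise_displacement(motion_trace(p2), 50)
  expect_equal(fd2$fd[3], 0.5)
})

test_that("the exclusion rule names every violated threshold", {
  zero <- motion_trace(matrix(0, 20, 6))
  fd0 <- compute_framewise_displacement(zero)
  expect_true(apply_exclusion_rule(zero, fd0)$included)

  p <- matrix(0, 20, 6); p[15:20, 2] <- 2.5
  m <- motion_trace(p)
  qc <- apply_exclusion_rule(m, compute_framewise_displacement(m))
  expect_false(qc$included)
  expect_match(qc$reasons, "translation", all = FALSE)
})

test_that("a cohort planted with 3 high-motion patients loses exactly 3", {
  spec <- tiny_spec(seed = 9, n_patients = 23L, n_controls = 20L,
                    n_volumes = 50L,
                    motion_plan = list(mean_fd_patients = 0.15,
                                       mean_fd_controls = 0.10,
                                       subject_jitter = 0.4,
                                       n_high_motion = 3L,
                                       high_motion_fd = 0.9))
  co <- generate_cohort(spec)
  decisions <- vapply(co$motions, function(m)
    apply_exclusion_rule(m, compute_framewise_displacement(m))$included,
    logical(1))
  expect_equal(sum(!decisions), 3L)
  expect_equal(which(!decisions), 1:3)    # planted on the first patients
})

test_that("nuisance regression matches a normal-equations oracle", {
  run <- random_run(5, grid = c(4L, 4L, 4L), nt = 40L)
  # intercept-only = demeaning
  dm <- regress_nuisance(run)
  expect_equal(dm$data[2, 3, 1, ],
               run$data[2, 3, 1, ] - mean(run$data[2, 3, 1, ]))

  # a voxel equal to a regressor is annihilated
  reg <- withr::with_seed(8, matrix(rnorm(40 * 6), 40, 6))
  run2 <- run
  run2$data[1, 1, 1, ] <- reg[, 3]
  out <- regress_nuisance(run2, reg)
  expect_lt(max(abs(out$data[1, 1, 1, ])), 1e-10)

  # full fit equals the hand-rolled (X'X)^-1 X' y residual at every voxel
  X <- cbind(1, reg)
  beta_hat <- solve(t(X) %*% X) %*% t(X)
  for (v in list(c(2, 2, 2), c(4, 1, 3))) {
    y <- run2$data[v[1], v[2], v[3], ]
    res_oracle <- y - X %*% (beta_hat %*% y)
    expect_equal(out$data[v[1], v[2], v[3], ], as.numeric(res_oracle),
                 tolerance = 1e-8)
  }
  # residuals orthogonal to each regressor
  Y <- matrix(out$data, 64, 40)
  expect_lt(max(abs(Y %*% reg)) / max(abs(Y)), 1e-8)

  expect_error(regress_nuisance(run, cbind(reg, reg[, 1])),
               "rank deficient")
})

test_that("the band-pass keeps in-band and rejects out-of-band sinusoids", {
  nt <- 100L; tr <- 2
  t_s <- (0:(nt - 1)) * tr
  mk <- function(f) bold_run(array(rep(sin(2 * pi * f * t_s),
                                       each = 8), c(2, 2, 2, nt)), tr)
  inb <- bandpass_filter(mk(0.05), 0.01, 0.08)
  expect_gt(cor(inb$data[1, 1, 1, ], sin(2 * pi * 0.05 * t_s)), 0.99)
  outb <- bandpass_filter(mk(0.2), 0.01, 0.08)
  expect_lt(var(outb$data[1, 1, 1, ]) / var(sin(2 * pi * 0.2 * t_s)), 0.01)
  expect_error(bandpass_filter(mk(0.05), 0.01, 0.3), "Nyquist")
})

test_that("filtered white noise has spectral support inside the band", {
  run <- random_run(3, grid = c(2L, 2L, 2L), nt = 128L, tr = 2)
  out <- bandpass_filter(run, 0.01, 0.08)
  y <- out$data[1, 1, 1, ]
  spec <- Mod(fft(y))^2
  freq <- pmin(0:127, 128 - (0:127)) / (128 * 2)
  inband <- freq >= 0.01 & freq <= 0.08
  expect_gt(sum(spec[inband]) / sum(spec), 1 - 1e-10)
})

test_that("preprocessing leaves no flat voxels on synthetic runs", {
  co <- generate_cohort(tiny_spec(seed = 6, n_volumes = 40L))
  prep <- preprocess_run(co$runs[[1]], co$motions[[1]], drop_volumes = 10)
  expect_length(prep$flat_voxels, 0)
  expect_equal(n_volumes(prep$run), 30L)
  expect_equal(nrow(prep$motion$params), 30L)
})
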