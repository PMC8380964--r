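# Synthetic two-group rs-fMRI cohort generator.
#
# Coupling model: every in-network voxel time series is
#   x = noise_sd * ( sqrt(w) * latent + sqrt(1 - w) * eps )
# with a per-subject latent signal and voxel noise both band-limited to
# [0.01, 0.08] Hz (so temporal preprocessing leaves the correlation
# structure invariant).  Two voxels in regions with weights w1, w2
# then have true correlation sqrt(w1 * w2) (= w within one region), which
# gives closed-form expected NH values usable as analytic oracles.

#' Specify a synthetic rs-fMRI cohort
#'
#' Defines the study conditions for [generate_cohort()]: grid, timing, group
#' sizes, the labeled voxel boxes composing the network, planted coupling
#' effects for the patient group, planted phenotype correlations, and the
#' motion plan. Defaults describe a two-group case-control design at desk
#' scale (18x22x18 grid, 100 volumes, TR 2 s, 20 patients + 20 controls)
#' with a contiguous four-region network, one planted NH increase and one
#' planted decrease in patients, and phenotype variables correlated with
#' regional NH at plausible magnitudes.
#'
#' @param grid_shape Integer vector of 3 positive voxel counts.
#' @param voxel_size_mm Isotropic voxel size in mm.
#' @param n_volumes Number of time points (>= 20).
#' @param tr_s Repetition time in seconds.
#' @param n_patients,n_controls Group sizes (>= 4).
#' @param network_regions List of labeled boxes, each
#'   `list(label=, x=c(lo,hi), y=c(lo,hi), z=c(lo,hi))` in 1-based inclusive
#'   voxel indices.
#' @param effect_regions List of `list(label=, sign=+1/-1, delta=)` coupling
#'   shifts applied to patients in the named region.
#' @param phenotype_plan List of `list(variable=, region=, r=)` planted
#'   correlations (|r| < 1) between a phenotype variable and patients' true
#'   regional mean NH.
#' @param motion_plan List with `mean_fd_patients`, `mean_fd_controls`
#'   (target mean framewise displacement in mm), `subject_jitter`
#'   (multiplicative spread), `n_high_motion` (patients planted above the
#'   exclusion threshold) and `high_motion_fd`.
#' @param base_coupling Baseline within-region coupling weight w in (0, 1).
#' @param subject_coupling_sd Between-subject SD of the per-region coupling
#'   weight (gives regional NH its across-subject variance).
#' @param fd_confound Coupling added per mm of a subject's realized mean FD
#'   (0 = no motion artifact; used to demonstrate covariate adjustment).
#' @param noise_sd Voxel noise standard deviation (> 0).
#' @param missing_fraction Missing-at-random fraction for clinical variables.
#' @param seed Integer seed; the full cohort is a pure function of the spec.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(grid_shape = c(18L, 22L, 18L),
                     voxel_size_mm = 4,
                     n_volumes = 100L,
                     tr_s = 2,
                     n_patients = 20L,
                     n_controls = 20L,
                     network_regions = default_network_regions(),
                     effect_regions = default_effect_regions(),
                     phenotype_plan = default_phenotype_plan(),
                     motion_plan = default_motion_plan(),
                     base_coupling = 0.4,
                     subject_coupling_sd = 0.03,
                     fd_confound = 0,
                     noise_sd = 1,
                     missing_fraction = 0,
                     seed = 1L) {
  spec <- structure(
    list(grid_shape = as.integer(grid_shape), voxel_size_mm = voxel_size_mm,
         n_volumes = as.integer(n_volumes), tr_s = tr_s,
         n_patients = as.integer(n_patients),
         n_controls = as.integer(n_controls),
         network_regions = network_regions, effect_regions = effect_regions,
         phenotype_plan = phenotype_plan, motion_plan = motion_plan,
         base_coupling = base_coupling,
         subject_coupling_sd = subject_coupling_sd,
         fd_confound = fd_confound, noise_sd = noise_sd,
         missing_fraction = missing_fraction, seed = as.integer(seed)),
    class = "sim_spec")
  validate_sim_spec(spec)
  spec
}

#' @rdname sim_spec
#' @export
default_network_regions <- function() {
  list(
    list(label = "mpfc",      x = c(7, 11), y = c(15, 19), z = c(10, 14)),
    list(label = "pcc",       x = c(7, 11), y = c(5, 9),   z = c(8, 12)),
    list(label = "precuneus", x = c(7, 11), y = c(4, 8),   z = c(14, 18)),
    list(label = "ltc",       x = c(2, 6),  y = c(8, 12),  z = c(8, 12)))
}

#' @rdname sim_spec
#' @export
default_effect_regions <- function() {
  # deltas sized for reliable cluster recovery at the desk-scale
  # acquisition (~26 effective temporal dof after band-limiting), giving
  # simulated peak |t| around 7-10 at n = 40
  list(list(label = "mpfc", sign = +1, delta = 0.40),
       list(label = "pcc",  sign = -1, delta = 0.30))
}

#' @rdname sim_spec
#' @export
default_phenotype_plan <- function() {
  list(
    list(variable = "TG",                   region = "mpfc",      r = -0.40),
    list(variable = "HDL_C",                region = "pcc",       r = -0.34),
    list(variable = "CHOL",                 region = "precuneus", r = 0.44),
    list(variable = "LDL_C",                region = "precuneus", r = 0.38),
    list(variable = "RBANS_verbal_fluency", region = "pcc",       r = 0.35),
    list(variable = "RBANS_verbal_total",   region = "pcc",       r = 0.34))
}

#' @rdname sim_spec
#' @export
default_motion_plan <- function() {
  list(mean_fd_patients = 0.15, mean_fd_controls = 0.10,
       subject_jitter = 0.4, n_high_motion = 0L, high_motion_fd = 0.9)
}

validate_sim_spec <- function(spec) {
  with(spec, {
    if (length(grid_shape) != 3L || any(grid_shape < 1L))
      stop("grid_shape must be 3 positive integers")
    if (!is.finite(voxel_size_mm) || voxel_size_mm <= 0)
      stop("voxel_size_mm must be positive")
    if (n_volumes < 20L) stop("n_volumes must be >= 20")
    if (!is.finite(tr_s) || tr_s <= 0) stop("tr_s must be positive")
    if (n_patients < 4L || n_controls < 4L)
      stop("each group needs at least 4 subjects")
    if (!is.finite(noise_sd) || noise_sd <= 0)
      stop("noise_sd must be > 0: zero noise makes all in-network series ",
           "identical across voxels (degenerate cohort)")
    if (base_coupling <= 0 || base_coupling >= 1)
      stop("base_coupling must lie in (0, 1)")
    if (missing_fraction < 0 || missing_fraction >= 1)
      stop("missing_fraction must lie in [0, 1)")
  })
  labels <- vapply(spec$network_regions, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("network region labels must be unique")
  for (rg in spec$network_regions) {
    for (ax in c("x", "y", "z")) {
      b <- rg[[ax]]
      if (length(b) != 2L || b[1] < 1L || b[1] > b[2])
        stop("malformed box for region ", rg$label)
    }
    if (rg$x[2] > spec$grid_shape[1] || rg$y[2] > spec$grid_shape[2] ||
        rg$z[2] > spec$grid_shape[3])
      stop("region ", rg$label, " extends outside the grid")
  }
  for (ef in spec$effect_regions) {
    if (!ef$label %in% labels)
      stop("effect region ", ef$label, " is not a network region")
    if (!ef$sign %in% c(-1, 1)) stop("effect sign must be +1 or -1")
    if (!is.finite(ef$delta) || ef$delta < 0)
      stop("effect delta must be a non-negative number")
  }
  ef_lab <- vapply(spec$effect_regions, `[[`, "", "label")
  ef_sgn <- vapply(spec$effect_regions, function(e) e$sign, numeric(1))
  for (l in unique(ef_lab))
    if (length(unique(ef_sgn[ef_lab == l])) > 1L)
      stop("effect region ", l, " has conflicting signs")
  boxes_overlap <- function(a, b)
    all(vapply(c("x", "y", "z"),
               function(ax) a[[ax]][1] <= b[[ax]][2] &&
                 b[[ax]][1] <= a[[ax]][2], logical(1)))
  if (length(spec$effect_regions) > 1L) {
    boxes <- lapply(ef_lab, function(l)
      spec$network_regions[[match(l, labels)]])
    for (i in seq_along(boxes)[-1]) for (j in seq_len(i - 1L))
      if (ef_sgn[i] != ef_sgn[j] && boxes_overlap(boxes[[i]], boxes[[j]]))
        stop("effect regions ", ef_lab[j], " and ", ef_lab[i],
             " overlap with conflicting signs")
  }
  for (pl in spec$phenotype_plan) {
    if (abs(pl$r) >= 1) stop("planted correlation must lie in (-1, 1)")
    if (!pl$region %in% labels)
      stop("phenotype plan targets unknown region ", pl$region)
  }
  pv <- vapply(spec$phenotype_plan, `[[`, "", "variable")
  if (anyDuplicated(pv))
    stop("each phenotype variable may target only one region")
  invisible(spec)
}

# region label per voxel: 0 = out of network, i = i-th region
region_label_array <- function(spec) {
  lab <- array(0L, dim = spec$grid_shape)
  for (i in seq_along(spec$network_regions)) {
    rg <- spec$network_regions[[i]]
    lab[rg$x[1]:rg$x[2], rg$y[1]:rg$y[2], rg$z[1]:rg$z[2]] <- i
  }
  lab
}

grid_affine <- function(spec) {
  v <- spec$voxel_size_mm
  aff <- diag(c(v, v, v, 1))
  aff[1:3, 4] <- -v * (spec$grid_shape - 1) / 2
  aff
}

# Band-limited Gaussian series (random-phase sinusoid mixtures supported
# exactly on [low, high] Hz), one per column, each standardized to sample
# mean 0 / sd 1.  Both the latent network signal and the voxel noise are
# drawn this way so that the band-pass step of temporal preprocessing
# leaves the cohort's correlation structure invariant.
band_limited_series <- function(n_volumes, tr_s, n_series, low = 0.01,
                                high = 0.08) {
  freq <- pmin(0:(n_volumes - 1), n_volumes - (0:(n_volumes - 1))) /
    (n_volumes * tr_s)
  keep <- freq >= low & freq <= high
  if (!any(keep))
    stop("no Fourier bin falls in [", low, ", ", high,
         "] Hz at this n_volumes/tr_s")
  W <- matrix(stats::rnorm(n_volumes * n_series), n_volumes, n_series)
  F <- stats::mvfft(W)
  F[!keep, ] <- 0
  X <- Re(stats::mvfft(F, inverse = TRUE)) / n_volumes
  X <- sweep(X, 2L, colMeans(X))
  sdv <- sqrt(colSums(X^2) / (n_volumes - 1L))
  sweep(X, 2L, sdv, "/")
}

latent_signal <- function(n_volumes, tr_s, low = 0.01, high = 0.08) {
  band_limited_series(n_volumes, tr_s, 1L, low, high)[, 1L]
}

# closed-form true regional mean NH given per-region weights w (vector over
# regions) and region sizes n: for a voxel in region R,
#   NH = [(n_R - 1) w_R + sum_{R' != R} n_R' sqrt(w_R w_R')] / (N - 1)
true_region_nh <- function(w, region_sizes) {
  N <- sum(region_sizes)
  vapply(seq_along(w), function(R) {
    cross <- sum(region_sizes[-R] * sqrt(w[R] * w[-R]))
    ((region_sizes[R] - 1) * w[R] + cross) / (N - 1)
  }, numeric(1))
}

#' Generate a synthetic two-group rs-fMRI cohort
#'
#' Produces one BOLD run, one motion trace and one phenotype row per
#' subject, together with the ground-truth network mask, planted effect
#' masks, per-subject true regional NH and planted correlations. The cohort
#' is a pure function of the spec: the same spec yields bit-identical data.
#'
#' @param spec A [sim_spec()].
#' @return An object of class `synthetic_cohort` with elements `runs`,
#'   `motions`, `phenotypes`, `mask_truth` and `truth`.
#' @export
generate_cohort <- function(spec) {
  validate_sim_spec(spec)
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(spec$seed)

  n_sub <- spec$n_patients + spec$n_controls
  group <- c(rep("patient", spec$n_patients), rep("control", spec$n_controls))
  ids <- sprintf("sub-%03d", seq_len(n_sub))
  labels <- vapply(spec$network_regions, `[[`, "", "label")
  n_reg <- length(labels)
  lab_arr <- region_label_array(spec)
  mask_ind <- lab_arr > 0L
  affine <- grid_affine(spec)
  region_sizes <- tabulate(lab_arr[mask_ind], nbins = n_reg)

  # per-subject per-region coupling weights
  w <- matrix(spec$base_coupling, n_sub, n_reg,
              dimnames = list(ids, labels))
  w <- w + matrix(stats::rnorm(n_sub * n_reg, 0, spec$subject_coupling_sd),
                  n_sub, n_reg)
  for (ef in spec$effect_regions) {
    j <- match(ef$label, labels)
    w[group == "patient", j] <- w[group == "patient", j] + ef$sign * ef$delta
  }
  w <- pmin(pmax(w, 0.02), 0.98)

  # motion: per-subject target mean FD, then simulated traces
  mp <- spec$motion_plan
  fd_target <- ifelse(group == "patient", mp$mean_fd_patients,
                      mp$mean_fd_controls)
  fd_target <- fd_target * stats::runif(n_sub, 1 - mp$subject_jitter,
                                        1 + mp$subject_jitter)
  if (mp$n_high_motion > 0L) {
    if (mp$n_high_motion > spec$n_patients)
      stop("n_high_motion exceeds the number of patients")
    fd_target[seq_len(mp$n_high_motion)] <- mp$high_motion_fd
  }
  motion_seeds <- sample.int(.Machine$integer.max, n_sub)
  motions <- vector("list", n_sub)
  mean_fd <- numeric(n_sub)
  for (s in seq_len(n_sub)) {
    sc <- motion_scale_for_fd(fd_target[s], spec$n_volumes)
    motions[[s]] <- generate_motion_trace(spec$n_volumes, sc, motion_seeds[s])
    mean_fd[s] <- compute_framewise_displacement(motions[[s]])$mean_fd
  }

  # motion-coupled artifact: coupling raised with realized mean FD
  w_eff <- pmin(pmax(w + spec$fd_confound * mean_fd, 0.02), 0.98)

  # BOLD runs
  mask_idx <- which(mask_ind)
  vox_region <- lab_arr[mask_idx]
  V <- prod(spec$grid_shape)
  runs <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    L <- latent_signal(spec$n_volumes, spec$tr_s)
    dat <- t(band_limited_series(spec$n_volumes, spec$tr_s, V))
    wv <- w_eff[s, vox_region]
    dat[mask_idx, ] <- sqrt(wv) %o% L +
      sqrt(1 - wv) * dat[mask_idx, , drop = FALSE]
    runs[[s]] <- bold_run(array(spec$noise_sd * dat,
                                c(spec$grid_shape, spec$n_volumes)),
                          tr_s = spec$tr_s, affine = affine,
                          subject_id = ids[s])
  }

  nh_true <- vapply(seq_len(n_sub),
                    function(s) true_region_nh(w_eff[s, ], region_sizes),
                    numeric(n_reg))
  nh_true <- if (n_reg == 1L) matrix(nh_true, ncol = 1L) else t(nh_true)
  dimnames(nh_true) <- list(ids, labels)

  effect_masks <- lapply(spec$effect_regions, function(ef) {
    m <- array(0L, dim = spec$grid_shape)
    m[lab_arr == match(ef$label, labels)] <- as.integer(ef$sign)
    m
  })
  names(effect_masks) <- vapply(spec$effect_regions, `[[`, "", "label")

  pheno_seed <- sample.int(.Machine$integer.max, 1L)
  phenotypes <- generate_phenotypes(spec, nh_true, pheno_seed,
                                    group = group, ids = ids,
                                    mean_fd = mean_fd)

  truth <- list(
    effect_masks = effect_masks,
    planted_correlations = do.call(rbind, lapply(spec$phenotype_plan,
      function(p) data.frame(variable = p$variable, region = p$region,
                             r = p$r))),
    true_mean_fd = stats::setNames(mean_fd, ids),
    true_region_nh = nh_true,
    coupling = w_eff,
    region_labels = lab_arr,
    region_names = labels)

  structure(list(runs = runs, motions = motions, phenotypes = phenotypes,
                 mask_truth = network_mask(mask_ind, affine),
                 truth = truth, spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_cohort: %d patients + %d controls, ",
                     "%d-voxel network, %d volumes @ TR %.3g s>\n"),
              x$spec$n_patients, x$spec$n_controls,
              x$mask_truth$n_voxels, x$spec$n_volumes, x$spec$tr_s))
  invisible(x)
}

#' Simulate a rigid-body motion trace
#'
#' Six mean-reverting random-walk series (AR(1), `rho`): three translations
#' in mm with innovation SD `scale` and three rotations in radians with
#' innovation SD `scale / head_radius_mm`, so translations and rotations
#' contribute equally to framewise displacement. `scale = 0` gives an
#' all-zero trace; for a fixed seed the trace is exactly linear in `scale`.
#'
#' @param n_volumes Number of volumes (>= 2).
#' @param scale Non-negative innovation SD in mm per step.
#' @param seed Integer seed.
#' @param rho AR(1) coefficient in [0, 1).
#' @param head_radius_mm Head radius linking rotations to displacement.
#' @return A [motion_trace()].
#' @export
generate_motion_trace <- function(n_volumes, scale, seed, rho = 0.95,
                                  head_radius_mm = 50) {
  if (n_volumes < 2L) stop("n_volumes must be >= 2")
  if (!is.finite(scale) || scale < 0) stop("scale must be non-negative")
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(seed)
  sds <- c(rep(scale, 3), rep(scale / head_radius_mm, 3))
  par <- matrix(0, n_volumes, 6L)
  innov <- matrix(stats::rnorm(n_volumes * 6L), n_volumes, 6L)
  for (t in 2:n_volumes)
    par[t, ] <- rho * par[t - 1L, ] + innov[t, ] * sds
  motion_trace(par)
}

#' Innovation scale that targets a mean framewise displacement
#'
#' Closed-form calibration for [generate_motion_trace()]: in the stationary
#' AR(1) model the expected FD per frame is
#' `6 * scale * sqrt(2 / (1 + rho)) * sqrt(2 / pi)`, and the subject mean
#' includes the zero first frame.
#'
#' @inheritParams generate_motion_trace
#' @param mean_fd_mm Target mean framewise displacement in mm.
#' @return The innovation scale (mm per step).
#' @export
motion_scale_for_fd <- function(mean_fd_mm, n_volumes, rho = 0.95) {
  if (mean_fd_mm < 0) stop("mean_fd_mm must be non-negative")
  per_frame <- 6 * sqrt(2 / (1 + rho)) * sqrt(2 / pi)
  mean_fd_mm * n_volumes / (n_volumes - 1) / per_frame
}

#' Generate phenotype variables with planted NH correlations
#'
#' Each planned variable is `mu + sd * (r * z + sqrt(1 - r^2) * eps)` where
#' `z` is the across-patient standardization of the target region's true
#' mean NH, so the population correlation with regional NH equals the
#' planted `r`. Unplanned variables are independent of NH.
#'
#' @param spec A [sim_spec()].
#' @param true_region_nh Matrix of true regional mean NH, one row per
#'   subject (patients first), columns named by region.
#' @param seed Integer seed.
#' @param group,ids,mean_fd Optional subject metadata; defaults follow the
#'   spec's group sizes.
#' @return A `data.frame` with one row per subject.
#' @export
generate_phenotypes <- function(spec, true_region_nh, seed, group = NULL,
                                ids = NULL, mean_fd = NULL) {
  for (pl in spec$phenotype_plan)
    if (abs(pl$r) >= 1) stop("planted correlation must lie in (-1, 1)")
  n_sub <- nrow(true_region_nh)
  if (is.null(group))
    group <- c(rep("patient", spec$n_patients),
               rep("control", n_sub - spec$n_patients))
  if (is.null(ids)) ids <- sprintf("sub-%03d", seq_len(n_sub))
  if (sum(group == "patient") < 3L)
    stop("need at least 3 patients to plant correlations")
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(seed)

  pat <- group == "patient"
  marginals <- list(
    TG = c(1.6, 0.6), CHOL = c(4.3, 0.8), HDL_C = c(1.25, 0.25),
    LDL_C = c(2.6, 0.7), RBANS_immediate_memory = c(88, 12),
    RBANS_verbal_fluency = c(90, 12), RBANS_verbal_total = c(89, 12),
    RBANS_total = c(88, 10))
  ph <- data.frame(subject_id = ids, group = group,
                   age = round(stats::runif(n_sub, 18, 42)),
                   sex = sample(c("M", "F"), n_sub, replace = TRUE),
                   education_yr = round(stats::runif(n_sub, 9, 16)),
                   illness_duration_yr =
                     ifelse(pat, round(stats::runif(n_sub, 0.2, 5), 1), NA),
                   HAMD17 = ifelse(pat,
                                   pmax(0, round(stats::rnorm(n_sub, 24, 4))),
                                   pmax(0, round(stats::rnorm(n_sub, 1.5, 1)))),
                   YMRS = ifelse(pat,
                                 pmax(0, round(stats::rnorm(n_sub, 8, 4))),
                                 pmax(0, round(stats::rnorm(n_sub, 1, 1)))),
                   HAMA14 = ifelse(pat,
                                   pmax(0, round(stats::rnorm(n_sub, 18, 5))),
                                   pmax(0, round(stats::rnorm(n_sub, 1.5, 1)))),
                   stringsAsFactors = FALSE)
  planted_vars <- vapply(spec$phenotype_plan, `[[`, "", "variable")
  for (v in names(marginals)) {
    mu <- marginals[[v]][1]; sd_v <- marginals[[v]][2]
    eps <- stats::rnorm(n_sub)
    if (v %in% planted_vars) {
      pl <- spec$phenotype_plan[[match(v, planted_vars)]]
      z <- rep(0, n_sub)
      z[pat] <- as.numeric(scale(true_region_nh[pat, pl$region]))
      val <- mu + sd_v * ifelse(pat, pl$r * z + sqrt(1 - pl$r^2) * eps, eps)
    } else {
      val <- mu + sd_v * eps
    }
    ph[[v]] <- round(val, 2)
  }
  if (!is.null(mean_fd)) ph$mean_fd <- mean_fd
  if (spec$missing_fraction > 0) {
    clin <- names(marginals)
    for (v in clin) {
      drop <- stats::runif(n_sub) < spec$missing_fraction
      ph[[v]][drop] <- NA
    }
  }
  ph
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}
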