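# Voxel-wise group comparison of NH maps with age and mean-FD covariates,
# and cluster-extent inference with a label-permutation max-extent null
# distribution (family-wise error control), Bonferroni-adjusted across the
# two signed contrasts.

#' Construct a group design
#'
#' @param subject_ids Character vector of subject identifiers.
#' @param group Character vector, each element "patient" or "control".
#' @param age Numeric age in years per subject.
#' @param mean_fd Numeric mean framewise displacement (mm) per subject.
#' @return An object of class `group_design`.
#' @export
group_design <- function(subject_ids, group, age, mean_fd) {
  n <- length(subject_ids)
  if (length(group) != n || length(age) != n || length(mean_fd) != n)
    stop("design columns have inconsistent lengths")
  if (!all(group %in% c("patient", "control")))
    stop("group labels must be 'patient' or 'control'")
  if (!any(group == "patient") || !any(group == "control"))
    stop("both groups must be non-empty")
  if (!all(is.finite(age)) || !all(is.finite(mean_fd)))
    stop("covariates must be complete and finite")
  structure(list(subject_ids = as.character(subject_ids), group = group,
                 age = as.numeric(age), mean_fd = as.numeric(mean_fd)),
            class = "group_design")
}

design_matrix <- function(design, use_covariates = TRUE) {
  g <- as.numeric(design$group == "patient")
  X <- if (use_covariates)
    cbind(intercept = 1, group = g, age = design$age,
          mean_fd = design$mean_fd)
  else cbind(intercept = 1, group = g)
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  X
}

nh_matrix <- function(nh_maps) {
  mask <- nh_maps[[1]]$mask
  std <- vapply(nh_maps, `[[`, logical(1), "standardized")
  if (length(unique(std)) > 1L)
    stop("NH maps mix standardized and raw values")
  for (m in nh_maps)
    if (!identical(dim(m$mask$indicator), dim(mask$indicator)) ||
        !identical(which(m$mask$indicator), which(mask$indicator)))
      stop("NH maps do not share one mask")
  Y <- t(vapply(nh_maps, nh_values, numeric(mask$n_voxels)))
  list(Y = Y, mask = mask, idx = which(mask$indicator))
}

# group-coefficient t statistics for all voxels at once
glm_group_t <- function(X, Y, coef = 2L) {
  XtXi <- solve(crossprod(X))
  B <- XtXi %*% crossprod(X, Y)          # p x V
  R <- Y - X %*% B
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(R^2) / df
  se <- sqrt(sigma2 * XtXi[coef, coef])
  list(t = as.numeric(B[coef, ] / se), df = df)
}

#' Voxel-wise GLM of NH on group with covariates
#'
#' Per voxel, ordinary least squares of NH on intercept, group indicator
#' (patient = 1, so positive t means patients > controls), age and mean
#' FD; returns the group-coefficient t statistic map.
#'
#' @param nh_maps List of `nh_map` (one per design row, same mask).
#' @param design A [group_design()].
#' @param use_covariates Include age and mean FD (default TRUE).
#' @return An object of class `tstat_map`: `t` (3D array, NA off-mask),
#'   `df`, `mask`.
#' @export
fit_voxelwise_glm <- function(nh_maps, design, use_covariates = TRUE) {
  stopifnot(inherits(design, "group_design"))
  nm <- nh_matrix(nh_maps)
  if (nrow(nm$Y) != length(design$group))
    stop("one NH map per design row is required")
  X <- design_matrix(design, use_covariates)
  if (nrow(X) <= ncol(X)) stop("more design columns than subjects")
  fit <- glm_group_t(X, nm$Y)
  tarr <- array(NA_real_, dim = dim(nm$mask$indicator))
  tarr[nm$idx] <- fit$t
  structure(list(t = tarr, df = fit$df, mask = nm$mask),
            class = "tstat_map")
}

signed_clusters <- function(tvals, idx, grid_dim, tcrit, connectivity) {
  out <- list()
  for (sgn in c(1, -1)) {
    supra <- if (sgn > 0) tvals >= tcrit else tvals <= -tcrit
    if (!any(supra)) next
    sidx <- idx[supra]
    lab <- label_components(sidx, grid_dim, connectivity)
    for (l in seq_len(max(lab)))
      out[[length(out) + 1L]] <- list(sign = sgn, idx = sidx[lab == l],
                                      t = tvals[supra][lab == l])
  }
  out
}

max_cluster_extent <- function(tvals, idx, grid_dim, tcrit, connectivity) {
  best <- 0L
  for (sgn in c(1, -1)) {
    supra <- if (sgn > 0) tvals >= tcrit else tvals <= -tcrit
    if (!any(supra)) next
    lab <- label_components(idx[supra], grid_dim, connectivity)
    best <- max(best, tabulate(lab))
  }
  best
}

#' Cluster-extent inference with a permutation FWE null
#'
#' Thresholds the observed group-t map at the two-tailed `voxel_p`
#' critical value, forms signed supra-threshold clusters (26-connectivity
#' by default), and compares each cluster's extent against the null
#' distribution of the maximum cluster extent obtained by refitting the
#' GLM under `n_perm` random permutations of the group labels (covariates
#' stay with their subjects). Cluster
#' `FWE p = (1 + #[perm max extent >= observed]) / (1 + n_perm)`, then
#' Bonferroni-doubled across the two signed contrasts; clusters with
#' adjusted p below `alpha` are reported with their peak voxel converted
#' to world mm through the mask affine.
#'
#' @param nh_maps List of `nh_map` objects (one per subject).
#' @param design A [group_design()].
#' @param voxel_p Two-tailed cluster-forming voxel p (default 0.001).
#' @param n_perm Number of permutations (>= 100).
#' @param alpha Cluster-level significance (default 0.05).
#' @param seed Integer seed for the permutations.
#' @param use_covariates Include age and mean FD (default TRUE).
#' @param bonferroni_signs Double p across the two contrasts (default
#'   TRUE).
#' @param connectivity 6 or 26.
#' @return An object of class `cluster_table`: a data.frame with one row
#'   per significant cluster (direction, peak x/y/z mm, extent, peak t,
#'   fwe_p) plus attributes `tstat_map`, `cluster_labels` (3D integer
#'   array), `null_max_extent`, `all_clusters`.
#' @export
cluster_extent_inference <- function(nh_maps, design, voxel_p = 0.001,
                                     n_perm = 1000L, alpha = 0.05,
                                     seed = 1L, use_covariates = TRUE,
                                     bonferroni_signs = TRUE,
                                     connectivity = 26L) {
  stopifnot(inherits(design, "group_design"))
  if (voxel_p <= 0 || voxel_p >= 1) stop("voxel_p must lie in (0, 1)")
  if (n_perm < 100L) stop("use at least 100 permutations")
  if ((1 + if (bonferroni_signs) 1 else 0) / (1 + n_perm) > alpha)
    warning("n_perm = ", n_perm, " is barely enough resolution for alpha = ",
            alpha)
  nm <- nh_matrix(nh_maps)
  grid_dim <- dim(nm$mask$indicator)
  X <- design_matrix(design, use_covariates)
  obs <- glm_group_t(X, nm$Y)
  tcrit <- stats::qt(1 - voxel_p / 2, obs$df)
  clusters <- signed_clusters(obs$t, nm$idx, grid_dim, tcrit, connectivity)

  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(seed)
  n <- nrow(X)
  null_max <- integer(n_perm)
  Xp <- X
  for (p_i in seq_len(n_perm)) {
    Xp[, 2L] <- X[sample.int(n), 2L]
    if (qr(Xp)$rank < ncol(Xp)) {          # degenerate shuffle; redraw
      Xp[, 2L] <- X[sample.int(n), 2L]
    }
    pt <- glm_group_t(Xp, nm$Y)
    null_max[p_i] <- max_cluster_extent(pt$t, nm$idx, grid_dim, tcrit,
                                        connectivity)
  }

  rows <- list()
  lab_arr <- array(0L, dim = grid_dim)
  all_rows <- list()
  aff <- nm$mask$affine
  for (cl in clusters) {
    ext <- length(cl$idx)
    p_raw <- (1 + sum(null_max >= ext)) / (1 + n_perm)
    p_adj <- min(1, p_raw * (if (bonferroni_signs) 2 else 1))
    pk <- which.max(abs(cl$t))
    peak_idx <- cl$idx[pk]
    co <- arrayInd(peak_idx, grid_dim)
    mm <- aff %*% c(co - 1L, 1)
    row <- data.frame(
      direction = if (cl$sign > 0) "patients>controls" else
        "patients<controls",
      peak_x_mm = round(mm[1], 1), peak_y_mm = round(mm[2], 1),
      peak_z_mm = round(mm[3], 1),
      extent = ext, peak_t = cl$t[pk], fwe_p = p_adj,
      stringsAsFactors = FALSE)
    all_rows[[length(all_rows) + 1L]] <- row
    if (p_adj < alpha) {
      rows[[length(rows) + 1L]] <- row
      lab_arr[cl$idx] <- length(rows) * cl$sign
    }
  }
  tbl <- if (length(rows)) do.call(rbind, rows) else
    data.frame(direction = character(0), peak_x_mm = numeric(0),
               peak_y_mm = numeric(0), peak_z_mm = numeric(0),
               extent = integer(0), peak_t = numeric(0),
               fwe_p = numeric(0), stringsAsFactors = FALSE)
  if (nrow(tbl)) {
    ord <- order(-tbl$extent)
    relab <- array(0L, dim = grid_dim)
    for (new_i in seq_along(ord))
      relab[abs(lab_arr) == ord[new_i]] <-
        new_i * sign(2 * (tbl$direction[ord[new_i]] == "patients>controls")
                     - 1)
    lab_arr <- relab
    tbl <- tbl[ord, , drop = FALSE]
    rownames(tbl) <- NULL
    tbl$cluster <- sprintf("cluster%02d", seq_len(nrow(tbl)))
    tbl <- tbl[, c("cluster", "direction", "peak_x_mm", "peak_y_mm",
                   "peak_z_mm", "extent", "peak_t", "fwe_p")]
  } else {
    tbl$cluster <- character(0)
    tbl <- tbl[, c("cluster", "direction", "peak_x_mm", "peak_y_mm",
                   "peak_z_mm", "extent", "peak_t", "fwe_p")]
  }
  tmap <- array(NA_real_, dim = grid_dim)
  tmap[nm$idx] <- obs$t
  structure(tbl,
            class = c("cluster_table", "data.frame"),
            tstat_map = structure(list(t = tmap, df = obs$df,
                                       mask = nm$mask),
                                  class = "tstat_map"),
            cluster_labels = lab_arr,
            null_max_extent = null_max,
            all_clusters = if (length(all_rows)) do.call(rbind, all_rows)
            else NULL,
            tcrit = tcrit)
}

#' Permutation p-value from exceedance counts
#'
#' `p = (1 + #[null >= observed]) / (1 + n_perm)`.
#'
#' @param n_exceed Number of permutations reaching the observed statistic.
#' @param n_perm Number of permutations.
#' @return The permutation p-value.
#' @export
permutation_pvalue <- function(n_exceed, n_perm) {
  (1 + n_exceed) / (1 + n_perm)
}

#' Per-subject mean NH over each significant cluster
#'
#' @param nh_maps List of `nh_map` objects.
#' @param clusters A `cluster_table` from [cluster_extent_inference()].
#' @return A data.frame: one row per subject (column `subject_id` taken
#'   from the maps), one column per cluster.
#' @export
extract_region_means <- function(nh_maps, clusters) {
  stopifnot(inherits(clusters, "cluster_table"))
  if (nrow(clusters) == 0L) stop("cluster table is empty")
  lab <- attr(clusters, "cluster_labels")
  nm <- nh_matrix(nh_maps)
  out <- data.frame(subject_id = vapply(nh_maps, `[[`, "", "subject_id"),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(clusters))) {
    cidx <- which(abs(lab) == i)
    if (!length(cidx)) stop("cluster ", i, " has no voxels")
    cols <- match(cidx, nm$idx)
    out[[clusters$cluster[i]]] <- rowMeans(nm$Y[, cols, drop = FALSE])
  }
  out
}
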