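# Network-mask derivation by temporal-concatenation group spatial ICA on
# control-group runs, template-matched component selection, and
# threshold-plus-cluster-filter binarization.
#
# The ICA is the classic fixed-point negentropy-maximizing algorithm
# (symmetric decorrelation, tanh contrast) applied to the PCA-reduced
# voxels-by-time matrix, so components are spatially independent maps.

#' Concatenate runs and reduce with PCA
#'
#' Builds the voxels x time matrix of in-mask series concatenated across
#' subjects (each voxel series z-scored within subject, the usual
#' variance normalization) and projects it on the top `k` principal
#' directions of its time-time covariance.
#'
#' @param runs List of [bold_run()] on identical grids.
#' @param brain_mask A [network_mask()] delimiting the voxels entering the
#'   decomposition (for synthetic data, typically the whole grid or the
#'   generator's mask).
#' @param k Number of principal components (< total concatenated volumes).
#' @return A list of class `reduced_data`: `scores` (voxels x k),
#'   `explained` (variance fraction retained), `mask`, `grid_dim`.
#' @export
concatenate_and_reduce <- function(runs, brain_mask, k) {
  if (length(runs) < 2L) stop("need at least 2 runs")
  for (r in runs) check_same_grid(r, brain_mask)
  idx <- which(brain_mask$indicator)
  mats <- lapply(runs, function(r) {
    d <- dim(r$data)
    M <- matrix(r$data, prod(d[1:3]), d[4])[idx, , drop = FALSE]
    mu <- rowMeans(M)
    sdv <- sqrt(voxel_variances(M))
    if (any(sdv < .Machine$double.eps))
      stop("zero-variance voxel series in run ", r$subject_id)
    (M - mu) / sdv
  })
  X <- do.call(cbind, mats)
  total_t <- ncol(X)
  if (k >= total_t) stop("k must be smaller than the total volume count")
  C <- crossprod(X)                     # time x time
  eg <- eigen(C, symmetric = TRUE)
  keep <- seq_len(k)
  scores <- X %*% eg$vectors[, keep, drop = FALSE]
  structure(list(scores = scores,
                 explained = sum(eg$values[keep]) / sum(pmax(eg$values, 0)),
                 mask = brain_mask,
                 grid_dim = dim(brain_mask$indicator)),
            class = "reduced_data")
}

#' Spatial ICA on a reduced data matrix
#'
#' Fixed-point (FastICA-type) estimation of spatially independent
#' components: the voxels x k score matrix is whitened over its k columns
#' and unmixed with symmetric decorrelation using the tanh contrast. Each
#' component map is z-scored over voxels and its sign fixed so the map's
#' skewness is positive.
#'
#' @param reduced A `reduced_data` from [concatenate_and_reduce()].
#' @param n_components Number of components to extract (<= k).
#' @param seed Integer seed for the random orthogonal initialization.
#' @param max_iter,tol Fixed-point iteration limit and convergence
#'   tolerance.
#' @param restarts Number of random initializations; the run whose most
#'   non-Gaussian component has the highest negentropy proxy is kept.
#' @return An object of class `component_set`: `maps` (list of 3D z-maps),
#'   `n_components`, `mask`, `converged`, `iterations`.
#' @export
spatial_ica <- function(reduced, n_components, seed = 1L, max_iter = 1000L,
                        tol = 1e-6, restarts = 5L) {
  stopifnot(inherits(reduced, "reduced_data"))
  X <- reduced$scores
  k <- ncol(X)
  if (n_components > k)
    stop("n_components (", n_components, ") exceeds the reduced rank (",
         k, ")")
  V <- nrow(X)
  Xc <- sweep(X, 2L, colMeans(X))
  eg <- eigen(crossprod(Xc) / V, symmetric = TRUE)
  if (any(eg$values[seq_len(n_components)] < 1e-12))
    stop("reduced data are rank deficient; lower n_components")
  Kw <- eg$vectors[, seq_len(n_components), drop = FALSE] %*%
    diag(1 / sqrt(eg$values[seq_len(n_components)]), n_components)
  Z <- Xc %*% Kw                         # V x c, whitened

  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(seed)

  sym_decorrelate <- function(W) {
    e <- eigen(W %*% t(W), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-300))) %*%
      t(e$vectors) %*% W
  }
  ica_once <- function(W) {
    W <- sym_decorrelate(W)
    it <- 0L; converged <- FALSE; delta <- Inf
    repeat {
      it <- it + 1L
      U <- Z %*% t(W)                    # V x c source estimates
      G <- tanh(U)
      W_new <- crossprod(G, Z) / V - diag(colMeans(1 - G^2)) %*% W
      W_new <- sym_decorrelate(W_new)
      delta <- max(abs(1 - abs(rowSums(W_new * W))))
      W <- W_new
      if (delta < tol) { converged <- TRUE; break }
      if (it >= max_iter) break
    }
    if (!all(is.finite(W)))
      stop("spatial ICA diverged after ", it, " iterations")
    S <- Z %*% t(W)
    # negentropy proxy per component: (E log cosh u - E log cosh Z)^2;
    # the restart whose best component is most non-Gaussian wins
    Su <- scale(S)
    J <- (colMeans(log(cosh(Su))) - 0.3745672)^2
    list(W = W, it = it, converged = converged, delta = delta,
         quality = max(J))
  }
  best <- NULL
  for (r in seq_len(max(1L, restarts))) {
    run <- ica_once(matrix(stats::rnorm(n_components^2), n_components))
    if (is.null(best) || run$quality > best$quality) best <- run
    # a decisively non-Gaussian component (log-cosh negentropy well above
    # anything a Gaussian map attains at these sizes) ends the search
    if (best$quality > 1e-3) break
  }
  if (!best$converged)
    # a spatially Gaussian minor subspace has no ICA fixed point and
    # cycles forever; the non-Gaussian components stabilise long before
    warning("spatial ICA did not reach tol ", tol, " after ", best$it,
            " iterations (final delta ", signif(best$delta, 3),
            "); returning the best of ", max(1L, restarts), " restarts")
  W <- best$W
  it <- best$it
  converged <- best$converged
  delta <- best$delta
  S <- Z %*% t(W)
  maps <- vector("list", n_components)
  idx <- which(reduced$mask$indicator)
  for (c_i in seq_len(n_components)) {
    s <- S[, c_i]
    s <- (s - mean(s)) / stats::sd(s)
    sk <- mean(s^3)
    if (sk < 0) s <- -s
    m <- array(NA_real_, dim = reduced$grid_dim)
    m[idx] <- s
    maps[[c_i]] <- m
  }
  structure(list(maps = maps, n_components = n_components,
                 mask = reduced$mask, converged = converged, iterations = it,
                 final_delta = delta),
            class = "component_set")
}

#' Select the component matching a network template
#'
#' Scores every component by the Pearson spatial correlation between its
#' absolute z-map and the template indicator over the decomposition mask,
#' and returns the argmax (ties broken by lowest index).
#'
#' @param components A `component_set` from [spatial_ica()].
#' @param template A [network_mask()] on the same grid.
#' @return A list: `index`, `score`, and `scores` for all components.
#' @export
select_network_component <- function(components, template) {
  stopifnot(inherits(components, "component_set"),
            inherits(template, "network_mask"))
  if (!identical(dim(template$indicator),
                 dim(components$mask$indicator)))
    stop("template grid does not match the component maps")
  if (template$n_voxels == 0L) stop("template mask is empty")
  idx <- which(components$mask$indicator)
  tmpl <- as.numeric(template$indicator[idx])
  if (stats::sd(tmpl) == 0)
    stop("template has no contrast over the decomposition mask")
  scores <- vapply(components$maps, function(m) {
    v <- abs(m[idx])
    if (stats::sd(v) == 0) return(NA_real_)
    stats::cor(v, tmpl)
  }, numeric(1))
  if (all(is.na(scores)))
    stop("all component maps are constant (degenerate decomposition)")
  best <- which.max(replace(scores, is.na(scores), -Inf))
  list(index = best, score = scores[best], scores = scores)
}

#' Threshold a z-map into a binary network mask
#'
#' Keeps voxels with `z >= z_thresh`, removes connected components (26
#' connectivity by default) smaller than `min_cluster_voxels`, and returns
#' the result as a [network_mask()].
#'
#' @param map 3D z-scored component map (NA outside the decomposition
#'   mask).
#' @param z_thresh Positive z threshold.
#' @param min_cluster_voxels Minimum surviving component size.
#' @param affine 4x4 affine for the resulting mask.
#' @param connectivity 6 or 26.
#' @return A [network_mask()].
#' @export
threshold_to_mask <- function(map, z_thresh = 2.3, min_cluster_voxels = 10L,
                              affine = diag(4), connectivity = 26L) {
  if (!is.array(map) || length(dim(map)) != 3L)
    stop("`map` must be a 3D array")
  if (z_thresh <= 0) stop("z_thresh must be positive")
  idx <- which(!is.na(map) & map >= z_thresh)
  if (length(idx) < 2L)
    stop("no voxels survive z >= ", z_thresh,
         "; lower the threshold")
  lab <- label_components(idx, dim(map), connectivity)
  sizes <- tabulate(lab)
  keep <- idx[sizes[lab] >= min_cluster_voxels]
  if (length(keep) < 2L)
    stop("no cluster of >= ", min_cluster_voxels,
         " voxels survives z >= ", z_thresh, "; lower the threshold")
  ind <- array(FALSE, dim = dim(map))
  ind[keep] <- TRUE
  network_mask(ind, affine)
}

#' Derive a network mask from control runs by group ICA
#'
#' End-to-end wrapper: concatenate + PCA-reduce the control runs, run
#' spatial ICA, pick the component best matching the template, and
#' binarize it. Only the runs passed in enter the fit; callers are
#' expected to pass control-group runs exclusively, mirroring designs
#' where the network definition must not be influenced by patients.
#'
#' @param control_runs List of control [bold_run()].
#' @param template A [network_mask()] template of the sought network.
#' @param brain_mask Decomposition mask; defaults to the whole grid.
#' @param n_components Components to extract (default 20).
#' @param pca_k PCA dimension (default `n_components + 5`).
#' @param seed Integer seed.
#' @param z_thresh,min_cluster_voxels Binarization parameters.
#' @return A list: `mask` ([network_mask()]), `component` (3D z-map),
#'   `selection` (index/score), `components`, `explained`.
#' @export
derive_network_mask <- function(control_runs, template, brain_mask = NULL,
                                n_components = 20L, pca_k = n_components + 5L,
                                seed = 1L, z_thresh = 2.3,
                                min_cluster_voxels = 10L) {
  if (is.null(brain_mask)) {
    g <- dim(control_runs[[1]]$data)[1:3]
    brain_mask <- network_mask(array(TRUE, g), control_runs[[1]]$affine)
  }
  red <- concatenate_and_reduce(control_runs, brain_mask, pca_k)
  comp <- spatial_ica(red, n_components, seed = seed)
  sel <- select_network_component(comp, template)
  mask <- threshold_to_mask(comp$maps[[sel$index]], z_thresh,
                            min_cluster_voxels,
                            affine = brain_mask$affine)
  list(mask = mask, component = comp$maps[[sel$index]], selection = sel,
       components = comp, explained = red$explained)
}

#' Dice coefficient between two masks
#'
#' @param a,b [network_mask()] objects or logical arrays on one grid.
#' @return Dice similarity in [0, 1].
#' @export
dice_coefficient <- function(a, b) {
  ai <- if (inherits(a, "network_mask")) a$indicator else as.logical(a)
  bi <- if (inherits(b, "network_mask")) b$indicator else as.logical(b)
  if (!identical(dim(ai), dim(bi))) stop("masks are not on the same grid")
  2 * sum(ai & bi) / (sum(ai) + sum(bi))
}
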