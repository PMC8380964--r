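# Network homogeneity: for each voxel inside a network mask, the mean
# Pearson correlation of its time series with every other in-mask voxel's
# series.  The fast path uses the standardized-sum identity: with each
# series z-scored (sd denominator T-1), sum_j corr(x_i, x_j) equals
# x_i' q / (T-1) where q is the row sum of the standardized series, so the
# whole map costs O(N T) instead of O(N^2 T).

mask_matrix <- function(run, mask) {
  check_same_grid(run, mask)
  if (mask$n_voxels < 2L) stop("mask must contain at least 2 voxels")
  d <- dim(run$data)
  idx <- which(mask$indicator)
  M <- t(matrix(run$data, prod(d[1:3]), d[4])[idx, , drop = FALSE])  # T x N
  v <- apply(M, 2L, stats::var)
  if (any(v < .Machine$double.eps)) {
    bad <- idx[which(v < .Machine$double.eps)[1]]
    co <- arrayInd(bad, d[1:3])
    stop(sprintf("in-mask voxel (%d, %d, %d) has zero variance",
                 co[1], co[2], co[3]))
  }
  list(M = M, idx = idx, dim = d[1:3])
}

#' Compute the network homogeneity map
#'
#' `NH(i) = mean_{j != i} corr(x_i, x_j)` over the `N` in-mask voxels,
#' computed via the standardized-sum identity in O(N T).
#'
#' @param run A [bold_run()].
#' @param mask A [network_mask()] on the same grid.
#' @return An object of class `nh_map`: `values` (3D array, NA outside the
#'   mask), `mask`, `standardized = FALSE`, `subject_id`.
#' @export
compute_nh_map <- function(run, mask) {
  mm <- mask_matrix(run, mask)
  Tn <- nrow(mm$M); N <- ncol(mm$M)
  Z <- scale(mm$M)                       # T x N, unit sample sd
  q <- rowSums(Z)
  corr_sum <- as.numeric(crossprod(Z, q)) / (Tn - 1)
  nh <- (corr_sum - 1) / (N - 1)
  nh <- pmin(pmax(nh, -1), 1)
  vals <- array(NA_real_, dim = mm$dim)
  vals[mm$idx] <- nh
  structure(list(values = vals, mask = mask, standardized = FALSE,
                 subject_id = run$subject_id),
            class = "nh_map")
}

#' Brute-force NH reference implementation
#'
#' Builds the explicit N x N pairwise correlation matrix and averages each
#' row excluding the diagonal. Guarded to small masks; exists as the
#' independent oracle for [compute_nh_map()].
#'
#' @inheritParams compute_nh_map
#' @return An `nh_map`.
#' @export
nh_bruteforce_oracle <- function(run, mask) {
  if (mask$n_voxels > 2000L)
    stop("brute-force oracle is limited to masks of <= 2000 voxels")
  mm <- mask_matrix(run, mask)
  C <- stats::cor(mm$M)
  nh <- (rowSums(C) - 1) / (ncol(C) - 1)
  vals <- array(NA_real_, dim = mm$dim)
  vals[mm$idx] <- nh
  structure(list(values = vals, mask = mask, standardized = FALSE,
                 subject_id = run$subject_id),
            class = "nh_map")
}

#' Standardize an NH map over the mask
#'
#' Z-scores the in-mask values (subtract the mask mean, divide by the mask
#' SD), removing per-subject scale and offset before group statistics.
#'
#' @param nh A raw `nh_map`.
#' @return The standardized `nh_map` (flagged `standardized = TRUE`).
#' @export
standardize_nh_map <- function(nh) {
  stopifnot(inherits(nh, "nh_map"))
  if (nh$standardized) stop("NH map is already standardized")
  idx <- which(nh$mask$indicator)
  v <- nh$values[idx]
  s <- stats::sd(v)
  if (!is.finite(s) || s < .Machine$double.eps)
    stop("NH map is constant over the mask; cannot standardize")
  nh$values[idx] <- (v - mean(v)) / s
  nh$standardized <- TRUE
  nh
}

#' In-mask values of an NH map
#'
#' @param nh An `nh_map`.
#' @return Numeric vector of the NH values at in-mask voxels (mask order).
#' @export
nh_values <- function(nh) {
  stopifnot(inherits(nh, "nh_map"))
  nh$values[which(nh$mask$indicator)]
}

#' @export
print.nh_map <- function(x, ...) {
  v <- nh_values(x)
  cat(sprintf("<nh_map %s: %d voxels, %s, range [%.3f, %.3f]>\n",
              x$subject_id, length(v),
              if (x$standardized) "standardized" else "raw",
              min(v), max(v)))
  invisible(x)
}
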