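#' @keywords internal
"_PACKAGE"

#' Construct a BOLD run
#'
#' A BOLD run is one subject's 4D resting-state acquisition: a real-valued
#' array indexed (x, y, z, t) together with the repetition time and the
#' voxel-index-to-millimetre affine.
#'
#' @param data 4D numeric array, dimensions (x, y, z, t).
#' @param tr_s Repetition time in seconds (positive).
#' @param affine 4x4 voxel-index (0-based) to world-mm transform.
#' @param subject_id Subject identifier string.
#' @return An object of class `bold_run`.
#' @export
bold_run <- function(data, tr_s, affine = diag(4), subject_id = "unknown") {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("`data` must be a 4D array (x, y, z, t)")
  if (dim(data)[4] < 2L)
    stop("a BOLD run needs at least 2 volumes")
  if (!all(is.finite(data)))
    stop("BOLD data contain non-finite values")
  if (!is.numeric(tr_s) || length(tr_s) != 1L || !is.finite(tr_s) || tr_s <= 0)
    stop("`tr_s` must be a single positive number")
  affine <- as_affine(affine)
  structure(
    list(subject_id = as.character(subject_id), data = data,
         tr_s = tr_s, affine = affine),
    class = "bold_run")
}

as_affine <- function(affine) {
  affine <- matrix(as.numeric(affine), 4L, 4L)
  if (abs(det(affine)) < .Machine$double.eps * 100)
    stop("affine must be invertible")
  affine
}

#' Number of volumes in a BOLD run
#' @param run A `bold_run`.
#' @return Integer count of time points.
#' @export
n_volumes <- function(run) {
  stopifnot(inherits(run, "bold_run"))
  dim(run$data)[4]
}

#' @export
print.bold_run <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_run %s: %dx%dx%d voxels, %d volumes, TR %.3g s>\n",
              x$subject_id, d[1], d[2], d[3], d[4], x$tr_s))
  invisible(x)
}

#' Construct a binary network mask
#'
#' @param indicator 3D logical (or 0/1) array marking in-network voxels.
#' @param affine 4x4 voxel-index (0-based) to world-mm transform.
#' @return An object of class `network_mask`.
#' @export
network_mask <- function(indicator, affine = diag(4)) {
  if (!is.array(indicator) || length(dim(indicator)) != 3L)
    stop("`indicator` must be a 3D array")
  ind <- array(as.logical(indicator), dim = dim(indicator))
  if (anyNA(ind)) stop("mask indicator contains NA")
  if (sum(ind) < 2L) stop("a network mask needs at least 2 voxels")
  structure(list(indicator = ind, affine = as_affine(affine),
                 n_voxels = sum(ind)),
            class = "network_mask")
}

#' @export
print.network_mask <- function(x, ...) {
  d <- dim(x$indicator)
  cat(sprintf("<network_mask: %d voxels on a %dx%dx%d grid>\n",
              x$n_voxels, d[1], d[2], d[3]))
  invisible(x)
}

#' Construct a motion trace
#'
#' Six rigid-body realignment parameters per volume: three translations in
#' mm followed by three rotations in radians.
#'
#' @param params Numeric matrix with one row per volume and 6 columns.
#' @return An object of class `motion_trace`.
#' @export
motion_trace <- function(params) {
  params <- as.matrix(params)
  if (ncol(params) != 6L) stop("a motion trace has 6 columns")
  if (nrow(params) < 2L) stop("a motion trace needs at least 2 volumes")
  if (!all(is.finite(params))) stop("motion parameters contain non-finite values")
  colnames(params) <- c("tx_mm", "ty_mm", "tz_mm",
                        "rx_rad", "ry_rad", "rz_rad")
  structure(list(params = params), class = "motion_trace")
}

same_grid <- function(a_dim, a_aff, b_dim, b_aff, tol = 1e-6) {
  identical(as.integer(a_dim), as.integer(b_dim)) &&
    max(abs(a_aff - b_aff)) < tol
}

check_same_grid <- function(run, mask) {
  if (!same_grid(dim(run$data)[1:3], run$affine,
                 dim(mask$indicator), mask$affine))
    stop("run and mask are not on the same grid/affine")
  invisible(TRUE)
}
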