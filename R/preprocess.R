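# Temporal preprocessing and motion QC: drop initial volumes, nuisance
# regression, frequency-domain band-pass, Power framewise displacement and
# the 2 mm / 2 deg / mean-FD exclusion rule.  Spatial steps (realignment,
# normalization, smoothing) are out of scope: data are assumed to share a
# common grid already.

#' Drop initial volumes from a run
#'
#' Discards the first `k` volumes (scanner equilibration period).
#'
#' @param run A [bold_run()].
#' @param k Number of volumes to drop; at least 20 must remain.
#' @return The truncated [bold_run()].
#' @export
drop_initial_volumes <- function(run, k) {
  stopifnot(inherits(run, "bold_run"))
  k <- as.integer(k)
  nt <- n_volumes(run)
  if (k < 0L) stop("k must be non-negative")
  if (k > nt - 20L)
    stop("dropping ", k, " of ", nt, " volumes leaves fewer than 20")
  if (k == 0L) return(run)
  run$data <- run$data[, , , (k + 1L):nt, drop = FALSE]
  run
}

#' Drop initial rows from a motion trace
#'
#' Keeps a motion trace aligned with a run truncated by
#' [drop_initial_volumes()].
#'
#' @param motion A [motion_trace()].
#' @param k Number of leading rows to drop.
#' @return The truncated [motion_trace()].
#' @export
drop_initial_motion <- function(motion, k) {
  stopifnot(inherits(motion, "motion_trace"))
  k <- as.integer(k)
  if (k == 0L) return(motion)
  motion_trace(motion$params[-seq_len(k), , drop = FALSE])
}

#' Power framewise displacement
#'
#' `FD_t = sum(|delta translations|) + radius * sum(|delta rotations|)` for
#' `t >= 2`, with `FD_1 = 0`; rotations are converted to arc length on a
#' sphere of the given head radius. The subject summary `mean_fd` averages
#' over all volumes including the leading zero.
#'
#' @param motion A [motion_trace()].
#' @param head_radius_mm Head radius in mm (default 50).
#' @return An object of class `fd_series` with elements `fd` and `mean_fd`.
#' @export
compute_framewise_displacement <- function(motion, head_radius_mm = 50) {
  stopifnot(inherits(motion, "motion_trace"))
  p <- motion$params
  if (!all(is.finite(p))) stop("motion parameters contain non-finite values")
  d <- abs(diff(p))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
            head_radius_mm * rowSums(d[, 4:6, drop = FALSE]))
  structure(list(fd = fd, mean_fd = mean(fd)), class = "fd_series")
}

#' Motion exclusion rule
#'
#' A subject is excluded when any cumulative translation exceeds
#' `max_translation_mm`, any cumulative rotation exceeds `max_rotation_deg`,
#' or the mean framewise displacement exceeds `max_mean_fd_mm` (the classic
#' 2 mm / 2 degree rule plus a mean-FD cap). Every violated rule is named in
#' the decision's `reasons`.
#'
#' @param motion A [motion_trace()].
#' @param fd The matching `fd_series` from
#'   [compute_framewise_displacement()].
#' @param subject_id Subject identifier for the report.
#' @param max_translation_mm,max_rotation_deg,max_mean_fd_mm Thresholds.
#' @return An object of class `qc_decision`.
#' @export
apply_exclusion_rule <- function(motion, fd, subject_id = "unknown",
                                 max_translation_mm = 2,
                                 max_rotation_deg = 2,
                                 max_mean_fd_mm = 0.5) {
  stopifnot(inherits(motion, "motion_trace"), inherits(fd, "fd_series"))
  if (length(fd$fd) != nrow(motion$params))
    stop("FD series and motion trace have inconsistent lengths")
  max_t <- max(abs(motion$params[, 1:3]))
  max_r <- max(abs(motion$params[, 4:6])) * 180 / pi
  reasons <- character(0)
  if (max_t > max_translation_mm)
    reasons <- c(reasons, sprintf("translation %.2f mm exceeds %.2f mm",
                                  max_t, max_translation_mm))
  if (max_r > max_rotation_deg)
    reasons <- c(reasons, sprintf("rotation %.2f deg exceeds %.2f deg",
                                  max_r, max_rotation_deg))
  if (fd$mean_fd > max_mean_fd_mm)
    reasons <- c(reasons, sprintf("mean FD %.3f mm exceeds %.3f mm",
                                  fd$mean_fd, max_mean_fd_mm))
  structure(list(subject_id = subject_id, included = length(reasons) == 0L,
                 reasons = reasons, mean_fd = fd$mean_fd,
                 max_abs_translation_mm = max_t,
                 max_abs_rotation_deg = max_r),
            class = "qc_decision")
}

#' Regress nuisance signals out of a run
#'
#' Replaces every voxel time series with the residuals of an ordinary
#' least-squares fit on an intercept plus the given regressors (typically
#' the 6 motion parameters). With `regressors = NULL` the series are only
#' demeaned.
#'
#' @param run A [bold_run()].
#' @param regressors Numeric matrix with one row per volume, or `NULL`.
#' @return The residualized [bold_run()].
#' @export
regress_nuisance <- function(run, regressors = NULL) {
  stopifnot(inherits(run, "bold_run"))
  nt <- n_volumes(run)
  X <- matrix(1, nt, 1L)
  if (!is.null(regressors)) {
    regressors <- as.matrix(regressors)
    if (nrow(regressors) != nt)
      stop("regressor rows (", nrow(regressors),
           ") do not match n_volumes (", nt, ")")
    X <- cbind(X, regressors)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("nuisance design is rank deficient")
  d <- dim(run$data)
  Y <- matrix(run$data, prod(d[1:3]), d[4])
  res <- t(qr.resid(qx, t(Y)))
  run$data <- array(res, dim = d)
  run
}

#' Expand 6 motion parameters to the Friston 24-parameter set
#'
#' Current parameters, their one-volume lag, and the squares of both.
#'
#' @param motion A [motion_trace()].
#' @return A numeric matrix with 24 columns.
#' @export
friston24 <- function(motion) {
  stopifnot(inherits(motion, "motion_trace"))
  p <- motion$params
  lag <- rbind(0, p[-nrow(p), , drop = FALSE])
  cbind(p, lag, p^2, lag^2)
}

#' Frequency-domain band-pass filter
#'
#' Zeroes discrete-Fourier coefficients whose frequency falls outside
#' `[low_hz, high_hz]` (the DC term is removed whenever `low_hz > 0`) and
#' inverse-transforms. An in-band sinusoid passes essentially unchanged; an
#' out-of-band sinusoid is attenuated by orders of magnitude.
#'
#' @param run A [bold_run()].
#' @param low_hz,high_hz Pass band in Hz; `0 <= low < high < 1/(2 tr_s)`.
#' @return The filtered [bold_run()].
#' @export
bandpass_filter <- function(run, low_hz = 0.01, high_hz = 0.08) {
  stopifnot(inherits(run, "bold_run"))
  nyq <- 1 / (2 * run$tr_s)
  if (low_hz < 0 || low_hz >= high_hz || high_hz >= nyq)
    stop(sprintf("band [%g, %g] Hz must satisfy 0 <= low < high < %g (Nyquist)",
                 low_hz, high_hz, nyq))
  d <- dim(run$data)
  nt <- d[4]
  freq <- pmin(0:(nt - 1), nt - (0:(nt - 1))) / (nt * run$tr_s)
  keep <- freq >= low_hz & freq <= high_hz
  if (low_hz == 0) keep[1] <- TRUE
  Y <- t(matrix(run$data, prod(d[1:3]), nt))
  F <- stats::mvfft(Y)
  F[!keep, ] <- 0
  run$data <- array(t(Re(stats::mvfft(F, inverse = TRUE)) / nt), dim = d)
  run
}

#' Standard temporal preprocessing for one subject
#'
#' Fixed order: drop initial volumes, regress motion nuisance parameters,
#' band-pass filter. Flags (but does not alter) any voxel series left with
#' (near-)zero variance, which would make correlations downstream
#' undefined.
#'
#' @param run A [bold_run()].
#' @param motion The subject's [motion_trace()] (or `NULL` to skip motion
#'   regression).
#' @param drop_volumes Leading volumes to discard (default 10).
#' @param low_hz,high_hz Band-pass edges in Hz.
#' @param use_friston24 Expand the motion regressors to 24 parameters.
#' @return A list with the processed `run`, the truncated `motion`, and
#'   `flat_voxels` (linear indices of zero-variance series, normally
#'   integer(0)).
#' @export
preprocess_run <- function(run, motion = NULL, drop_volumes = 10L,
                           low_hz = 0.01, high_hz = 0.08,
                           use_friston24 = FALSE) {
  run <- drop_initial_volumes(run, drop_volumes)
  reg <- NULL
  if (!is.null(motion)) {
    motion <- drop_initial_motion(motion, drop_volumes)
    reg <- if (use_friston24) friston24(motion) else motion$params
    if (all(abs(reg) < .Machine$double.eps)) reg <- NULL  # zero motion
  }
  run <- regress_nuisance(run, reg)
  run <- bandpass_filter(run, low_hz, high_hz)
  d <- dim(run$data)
  v <- voxel_variances(matrix(run$data, prod(d[1:3]), d[4]))
  list(run = run, motion = motion,
       flat_voxels = which(v < .Machine$double.eps))
}

# variance of each voxel series (rows of a voxels x time matrix)
voxel_variances <- function(M) {
  mu <- rowMeans(M)
  rowSums((M - mu)^2) / (ncol(M) - 1L)
}
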