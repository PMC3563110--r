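#' Zero-phase band-pass filter for ROI time series
#'
#' Butterworth band-pass (default order 2) applied forward and backward
#' (zero phase) to each ROI channel, isolating the low-frequency band that
#' carries resting-state covariation. Channels are demeaned after
#' filtering.
#'
#' @param ts ROI x time matrix.
#' @param tr_seconds Repetition time (sampling interval) in seconds.
#' @param f_lo,f_hi Pass-band corner frequencies in Hz (defaults
#'   0.009-0.08).
#' @param order Butterworth order.
#' @return Filtered ROI x time matrix.
#' @export
bandpass <- function(ts, tr_seconds, f_lo = 0.009, f_hi = 0.08, order = 2) {
  ts <- as.matrix(ts)
  fs <- 1 / tr_seconds
  nyq <- fs / 2
  if (f_hi >= nyq)
    stop(sprintf("upper corner %g Hz is at/above Nyquist (%g Hz at TR = %gs)",
                 f_hi, nyq, tr_seconds))
  if (ncol(ts) < 4 * (2 * order))
    stop("time series too short for the requested filter order")
  bf <- signal::butter(order, c(f_lo, f_hi) / nyq, type = "pass")
  out <- t(apply(ts, 1, function(x) signal::filtfilt(bf, x)))
  out - rowMeans(out)
}

# backward-difference derivative with a leading zero, matching the
# frame-to-frame motion convention (first frame has no predecessor)
backward_diff <- function(x) {
  if (is.matrix(x)) rbind(0, diff(x)) else c(0, diff(x))
}

# frames x k design matrix from a vector/matrix of frame-wise covariates
as_frame_design <- function(covariates, n_frames) {
  if (is.null(covariates)) return(NULL)
  x <- if (is.matrix(covariates) || is.data.frame(covariates))
    as.matrix(covariates) else matrix(covariates, ncol = 1)
  if (nrow(x) != n_frames)
    stop(sprintf("covariates have %d rows but the series has %d frames",
                 nrow(x), n_frames))
  x
}

# OLS residuals of each row-series of ts on design X (frames x k, no
# intercept column; one is added). Errors on rank deficiency.
residualize <- function(ts, X, what = "covariate") {
  n <- ncol(ts)
  X1 <- cbind(`(intercept)` = 1, X)
  q <- qr(X1)
  if (q$rank < ncol(X1)) {
    dropped <- colnames(X1)[q$pivot[(q$rank + 1):ncol(X1)]]
    stop(sprintf("%s design is rank deficient; collinear column(s): %s",
                 what, paste(dropped, collapse = ", ")))
  }
  t(qr.resid(q, t(ts)))
}

#' Nuisance regression of ROI time series
#'
#' Removes, per ROI, the ordinary-least-squares projection onto the
#' nuisance channels (e.g. global, white-matter, and ventricular signal
#' analogs), their first-order backward-difference derivatives, and an
#' intercept.
#'
#' @param ts ROI x time matrix.
#' @param nuisance Nuisance channel x time matrix (or a single series).
#' @return Residual ROI x time matrix (demeaned by construction).
#' @export
nuisance_regress <- function(ts, nuisance) {
  ts <- as.matrix(ts)
  if (is.null(dim(nuisance))) nuisance <- matrix(nuisance, nrow = 1)
  nuisance <- as.matrix(nuisance)
  if (ncol(nuisance) != ncol(ts))
    stop("nuisance channels and time series differ in frame count")
  X <- cbind(t(nuisance), backward_diff(t(nuisance)))
  colnames(X) <- c(paste0("nuis", seq_len(nrow(nuisance))),
                   paste0("d_nuis", seq_len(nrow(nuisance))))
  residualize(ts, X, what = "nuisance")
}

new_connectivity_matrix <- function(r, n_frames_used, subject_id,
                                    eligible = TRUE) {
  z <- suppressWarnings(fisher_z(r))
  valid <- is.finite(z)
  diag(valid) <- FALSE
  z[!valid] <- NA_real_
  structure(list(r = r, z = z, valid = valid,
                 n_frames_used = as.integer(n_frames_used),
                 subject_id = subject_id, eligible = eligible),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf(
    "<connectivity_matrix> %s: %d ROIs, %d edges (%d valid), %d frames%s\n",
    x$subject_id, nrow(x$r), n_edges(nrow(x$r)),
    sum(edge_vector(x$valid)), x$n_frames_used,
    if (x$eligible) "" else " [ineligible]"))
  invisible(x)
}

#' Subject correlation matrix
#'
#' Pearson correlation of every ROI pair over the retained frames,
#' Fisher-transformed to z. Degenerate edges (constant channels, |r| = 1)
#' are carried as invalid rather than raising, so one bad channel does not
#' lose the subject. When fewer than `min_frames` frames remain the matrix
#' is flagged ineligible (not an error); procedure-specific eligibility
#' rules are applied separately.
#'
#' @param ts ROI x time matrix (already cleaned).
#' @param mask Optional [censor_mask()] (TRUE = keep).
#' @param min_frames Minimum retained frames for eligibility.
#' @param subject_id Label stored on the result.
#' @return A `connectivity_matrix` (fields `r`, `z`, `valid`,
#'   `n_frames_used`, `subject_id`, `eligible`).
#' @export
correlation_matrix <- function(ts, mask = NULL, min_frames = 30L,
                               subject_id = "subject") {
  ts <- as.matrix(ts)
  if (!is.null(mask)) {
    if (length(mask) != ncol(ts))
      stop("censor mask length does not match frame count")
    ts <- ts[, as.logical(mask), drop = FALSE]
  }
  n_used <- ncol(ts)
  if (n_used < 3)
    stop("fewer than 3 retained frames; correlation undefined")
  r <- suppressWarnings(stats::cor(t(ts)))
  # channels that are (numerically) constant yield meaningless
  # correlations; mark their edges invalid instead of propagating noise
  degen <- apply(ts, 1, stats::sd) < 1e-8
  r[degen, ] <- NA_real_
  r[, degen] <- NA_real_
  diag(r) <- 1
  new_connectivity_matrix(r, n_used, subject_id,
                          eligible = n_used >= min_frames)
}

#' Subject partial correlation matrix
#'
#' Correlation of each ROI pair after regressing frame-wise motion
#' covariates (plus an intercept) out of both series: used with the six
#' frame-to-frame rigid-body parameter series or with the FD series as a
#' single covariate. With an empty covariate set this reduces exactly to
#' the plain correlation.
#'
#' @param ts ROI x time matrix.
#' @param covariates Frame-wise covariates: vector of length T or a
#'   T x k matrix (frames in rows). `NULL` for none.
#' @param min_frames,subject_id As in [correlation_matrix()].
#' @return A `connectivity_matrix` of partial correlations.
#' @export
partial_correlation_matrix <- function(ts, covariates, min_frames = 30L,
                                       subject_id = "subject") {
  ts <- as.matrix(ts)
  X <- as_frame_design(covariates, ncol(ts))
  res <- if (is.null(X)) ts else residualize(ts, X, what = "partial-correlation")
  cm <- correlation_matrix(res, min_frames = min_frames,
                           subject_id = subject_id)
  cm$n_frames_used <- ncol(ts)
  cm
}

#' Per-edge Euclidean ROI distances
#'
#' Straight-line distance in mm between ROI centre-of-mass coordinates,
#' one value per edge in the canonical edge order.
#'
#' @param rois A `roi_set`.
#' @return Numeric vector of length `n_edges(nrow(rois))`.
#' @export
edge_distances <- function(rois) {
  coords <- as.matrix(rois[, c("x", "y", "z")])
  edge_vector(as.matrix(stats::dist(coords)))
}
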