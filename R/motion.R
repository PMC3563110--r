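#' Framewise displacement
#'
#' FD for frame i sums the absolute volume-to-volume changes of the six
#' rigid-body parameters, `FD_i = |d dx| + |d dy| + |d dz| + |d alpha| +
#' |d beta| + |d gamma|`, with each rotation delta converted from radians
#' to millimetres as arc length on a sphere of radius `radius_mm`
#' (approximately the distance from the cortex to the head centre). The
#' differences are backward; the first frame has no predecessor and its FD
#' is defined as 0.
#'
#' @param series A [realignment_series()] (rotations in radians).
#' @param radius_mm Sphere radius for the rotation conversion.
#' @return Numeric vector of per-frame FD (mm), first element 0.
#' @export
compute_fd <- function(series, radius_mm = 50) {
  p <- series$params
  if (nrow(p) < 2) stop("FD needs at least 2 frames")
  d <- abs(diff(p))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    radius_mm * rowSums(d[, 4:6, drop = FALSE])
  c(0, fd)
}

#' DVARS: RMS volume-to-volume signal change
#'
#' `DVARS_t = sqrt(mean over channels of (I_t - I_{t-1})^2)`, the spatial
#' root-mean-square of the backward temporal difference of the signal; the
#' first frame is defined as 0. Abrupt head displacement manifests as
#' large global signal change, so DVARS indexes motion directly from the
#' data.
#'
#' When `normalize = TRUE` the channels are first rescaled so the run's
#' median intensity is 1000 (a channel-level stand-in for whole-run
#' mode-1000 intensity normalization), putting the conventional censoring
#' threshold of 4 on a comparable footing across runs.
#'
#' @param channels Channel x time numeric matrix.
#' @param normalize Rescale run median intensity to 1000 before
#'   differencing.
#' @return Per-frame DVARS vector, first element 0.
#' @export
compute_dvars <- function(channels, normalize = FALSE) {
  channels <- as.matrix(channels)
  if (ncol(channels) < 2) stop("DVARS needs at least 2 frames")
  if (nrow(channels) < 1) stop("DVARS needs at least 1 channel")
  if (normalize) {
    med <- stats::median(channels)
    if (!is.finite(med) || med == 0) {
      warning("median intensity is 0; DVARS returned unnormalized")
    } else {
      channels <- channels * (1000 / med)
    }
  }
  d <- channels[, -1, drop = FALSE] - channels[, -ncol(channels), drop = FALSE]
  c(0, sqrt(colMeans(d^2)))
}

#' Run-level RMS movement
#'
#' Total RMS over a run: the square root of the frame-wise mean of the sum
#' of squared rigid-body parameters, rotations converted to mm at
#' `radius_mm`. Runs whose RMS strictly exceeds the exclusion threshold
#' (default 1.5 mm) are flagged for removal.
#'
#' @param series A [realignment_series()].
#' @param radius_mm Sphere radius for rotation conversion.
#' @param rms_exclusion Exclusion threshold (mm), strict `>`.
#' @return List with `rms_total` (mm) and logical `excluded`.
#' @export
compute_rms <- function(series, radius_mm = 50, rms_exclusion = 1.5) {
  p <- series$params
  if (nrow(p) < 1) stop("RMS needs at least 1 frame")
  p[, 4:6] <- p[, 4:6] * radius_mm
  rms <- sqrt(mean(rowSums(p^2)))
  list(rms_total = rms, excluded = rms > rms_exclusion)
}

#' Build a censor mask from a motion metric
#'
#' Frames whose metric strictly exceeds the threshold are removed, together
#' with `n_before` frames before and `n_after` frames after each trigger
#' (to absorb temporal blurring of the artifact by the band-pass filter).
#' Removal windows from multiple triggers are unioned and clipped to the
#' run bounds.
#'
#' @param metric Per-frame metric (FD or DVARS).
#' @param threshold Removal threshold (strict `>`); must be non-negative.
#' @param n_before,n_after Augmentation window (defaults 1 and 2).
#' @param source_metric Label stored on the mask.
#' @return A [censor_mask()] (TRUE = keep).
#' @export
make_censor_mask <- function(metric, threshold, n_before = 1L, n_after = 2L,
                             source_metric = "fd") {
  if (!is.finite(threshold) || threshold < 0)
    stop("censoring threshold must be a non-negative number")
  if (!all(is.finite(metric))) stop("metric series must be finite")
  n <- length(metric)
  keep <- rep(TRUE, n)
  for (i in which(metric > threshold)) {
    lo <- max(1L, i - as.integer(n_before))
    hi <- min(n, i + as.integer(n_after))
    keep[lo:hi] <- FALSE
  }
  censor_mask(keep, source_metric = source_metric, threshold = threshold)
}

#' Motion summary for one run
#'
#' Bundles FD, DVARS (when channel data are available), run RMS and the
#' censor mask implied by a configuration into one record.
#'
#' @param series A [realignment_series()].
#' @param channels Optional channel x time matrix for DVARS.
#' @param config An [fc_config()].
#' @param metric Which metric drives the censor mask, `"fd"` or `"dvars"`.
#' @return List of class `motion_trace` with elements `fd`, `dvars`,
#'   `rms_total`, `excluded`, `mask`, `mean_fd_pre`, `mean_fd_post`.
#' @export
motion_trace <- function(series, channels = NULL, config = fc_config(),
                         metric = c("fd", "dvars")) {
  metric <- match.arg(metric)
  fd <- compute_fd(series, radius_mm = config$radius_mm)
  dvars <- if (!is.null(channels)) compute_dvars(channels, normalize = TRUE)
  rms <- compute_rms(series, radius_mm = config$radius_mm,
                     rms_exclusion = config$rms_exclusion)
  if (metric == "dvars") {
    if (is.null(dvars)) stop("DVARS censoring requires channel data")
    mask <- make_censor_mask(dvars, config$dvars_threshold,
                             config$frames_before, config$frames_after,
                             source_metric = "dvars")
  } else {
    mask <- make_censor_mask(fd, config$fd_threshold,
                             config$frames_before, config$frames_after,
                             source_metric = "fd")
  }
  structure(list(fd = fd, dvars = dvars, rms_total = rms$rms_total,
                 excluded = rms$excluded, mask = mask,
                 mean_fd_pre = mean(fd),
                 mean_fd_post = if (any(mask)) mean(fd[mask]) else NA_real_),
            class = "motion_trace")
}

#' LOWESS diagnostic curve
#'
#' Locally weighted scatterplot smooth of one motion metric against
#' another (typically DVARS on FD), used to inspect the shape of the
#' motion-artifact relationship, e.g. the knee near 0.2 mm FD that
#' motivates the censoring threshold. Purely diagnostic; never feeds any
#' statistic.
#'
#' @param x,y Equal-length numeric vectors (at least 10 points).
#' @param bandwidth LOWESS smoother span.
#' @return Data frame with sorted `x` and smoothed `y`.
#' @export
lowess_diagnostic <- function(x, y, bandwidth = 0.3) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 10) stop("need at least 10 points")
  s <- stats::lowess(x, y, f = bandwidth)
  data.frame(x = s$x, y = s$y)
}
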