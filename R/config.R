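#' Pipeline configuration
#'
#' Collects every threshold the motion pipeline uses so that all procedures
#' share one source of truth. Defaults follow the study conditions:
#' frames with FD above 0.2 mm (or DVARS above 4, on a median-1000 intensity
#' scale) are censored together with 1 frame before and 2 after; runs moving
#' more than 1.5 mm RMS are excluded; rotations are converted to arc length
#' on a 50 mm sphere.
#'
#' @param fd_threshold Censoring threshold on framewise displacement (mm).
#' @param dvars_threshold Censoring threshold on DVARS (median-1000 units).
#' @param rms_exclusion Run-level RMS exclusion threshold (mm), strict `>`.
#' @param frames_before,frames_after Censor-mask augmentation around each
#'   supra-threshold frame.
#' @param radius_mm Sphere radius for rotation-to-mm conversion.
#' @param min_frames Minimum retained frames for a correlation matrix.
#' @param top_k_age Features kept per fold for SVR age prediction.
#' @param top_k_dx Features kept per fold for subtype classification.
#' @param fdr_q Benjamini-Hochberg false-discovery-rate level.
#' @param match_alpha Significance level below which motion matching keeps
#'   removing subjects.
#' @param poly_degree Degree of the distance polynomial used by the r-value
#'   correction procedure.
#' @param bandpass Logical; apply the 0.009-0.08 Hz band-pass during
#'   subject-level cleaning.
#' @param f_lo,f_hi Band-pass corner frequencies (Hz).
#' @param svr SVR hyperparameters, see [svr_config()].
#' @param svm SVM hyperparameters, see [svm_config()].
#' @param seed Integer seed used by stochastic pipeline stages.
#' @return A list of class `fc_config`.
#' @export
fc_config <- function(fd_threshold = 0.2,
                      dvars_threshold = 4,
                      rms_exclusion = 1.5,
                      frames_before = 1L,
                      frames_after = 2L,
                      radius_mm = 50,
                      min_frames = 30L,
                      top_k_age = 300L,
                      top_k_dx = 150L,
                      fdr_q = 0.05,
                      match_alpha = 0.05,
                      poly_degree = 3L,
                      bandpass = FALSE,
                      f_lo = 0.009,
                      f_hi = 0.08,
                      svr = svr_config(),
                      svm = svm_config(),
                      seed = 1L) {
  cfg <- list(fd_threshold = fd_threshold, dvars_threshold = dvars_threshold,
              rms_exclusion = rms_exclusion,
              frames_before = as.integer(frames_before),
              frames_after = as.integer(frames_after),
              radius_mm = radius_mm, min_frames = as.integer(min_frames),
              top_k_age = as.integer(top_k_age),
              top_k_dx = as.integer(top_k_dx),
              fdr_q = fdr_q, match_alpha = match_alpha,
              poly_degree = as.integer(poly_degree),
              bandpass = isTRUE(bandpass), f_lo = f_lo, f_hi = f_hi,
              svr = svr, svm = svm, seed = as.integer(seed))
  class(cfg) <- "fc_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys are rejected so that a typo in a threshold name cannot
#' silently fall back to a default.
#'
#' @param path YAML file; keys are the arguments of [fc_config()] (the
#'   `svr`/`svm` entries may be nested maps).
#' @return `fc_config` list.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(fc_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(raw$svr)) raw$svr <- do.call(svr_config, raw$svr)
  if (!is.null(raw$svm)) raw$svm <- do.call(svm_config, raw$svm)
  do.call(fc_config, raw)
}

#' SVR hyperparameters for age prediction
#'
#' Epsilon-insensitive support-vector regression with a radial basis
#' kernel `K(x, x') = exp(-||x - x'||^2 / (2 sigma^2))`. The nominally
#' infinite error penalty is realized as a large finite `C`.
#'
#' @param C Error penalty (hard-margin surrogate, default `1e6`).
#' @param epsilon Insensitivity tube width.
#' @param sigma RBF kernel width.
#' @param top_k Features retained per cross-validation fold.
#' @return List of class `svr_config`.
#' @export
svr_config <- function(C = 1e6, epsilon = 1e-5, sigma = 2, top_k = 300L) {
  stopifnot(C > 0, epsilon >= 0, sigma > 0)
  structure(list(C = C, epsilon = epsilon, sigma = sigma,
                 top_k = as.integer(top_k)),
            class = "svr_config")
}

#' SVM hyperparameters for subtype classification
#'
#' Soft-margin RBF support-vector classification; multiclass problems are
#' handled one-vs-rest with a winner-takes-all rule on the decision values.
#'
#' @param C Soft-margin penalty.
#' @param sigma RBF kernel width.
#' @param top_k Features retained per cross-validation fold.
#' @return List of class `svm_config`.
#' @export
svm_config <- function(C = 1, sigma = 2, top_k = 150L) {
  stopifnot(C > 0, sigma > 0)
  structure(list(C = C, sigma = sigma, top_k = as.integer(top_k)),
            class = "svm_config")
}

# libsvm parameterizes the RBF kernel as exp(-gamma ||x-x'||^2); the
# sigma-form used here corresponds to gamma = 1/(2 sigma^2).
rbf_gamma <- function(sigma) 1 / (2 * sigma^2)
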