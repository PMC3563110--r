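# The ten motion-correction procedures as one configurable strategy layer.
#
# Subject-level transforms clean the time series and/or censor frames and
# produce a connectivity matrix per subject; cohort-level actions (mean-FD
# covariate, motion matching) are returned as metadata consumed by the
# age-association stage.

.procedure_table <- list(
  P1  = list(transform = "regress6",     cohort = "none",
             eligibility = "none"),
  P2  = list(transform = "partial6",     cohort = "none",
             eligibility = "none"),
  P3  = list(transform = "partial_fd",   cohort = "none",
             eligibility = "none"),
  P4  = list(transform = "regress_ftf",  cohort = "none",
             eligibility = "none"),
  P5  = list(transform = "regress6",     cohort = "mean_fd_covariate",
             eligibility = "none"),
  P6  = list(transform = "regress6",     cohort = "fd_match",
             eligibility = "none"),
  P7  = list(transform = "censor_fd",    cohort = "none",
             eligibility = "lt60_removed"),
  P8  = list(transform = "censor_fd",    cohort = "fd_match_post",
             eligibility = "lt60_removed"),
  P9  = list(transform = "censor_dvars", cohort = "dvars_match_post",
             eligibility = "lt60_removed"),
  P10 = list(transform = "poly_correct", cohort = "none",
             eligibility = "ge40_remaining")
)

#' Specification of one motion-correction procedure
#'
#' The ten procedures:
#' P1 regression of the six rigid-body parameters during cleaning
#' (traditional correction); P2/P3 partial correlations with the six
#' frame-to-frame parameters / the FD series as covariates; P4 cleaning
#' regression with frame-to-frame parameters replacing the traditional
#' ones; P5 mean FD as a group-level covariate of the age correlation;
#' P6 subject removal ("matching") until mean FD is unrelated to age;
#' P7 FD > 0.2 mm volume censoring with 1-before/2-after augmentation;
#' P8 censoring plus matching on post-censor mean FD; P9 DVARS > 4
#' censoring plus matching on post-censor mean DVARS; P10 per-subject
#' polynomial correction of r values from the censoring-induced delta-r
#' versus distance relationship.
#'
#' @param id `"P1"` ... `"P10"`.
#' @return List of class `procedure_spec` with fields `id`,
#'   `transform`, `cohort`, `eligibility`.
#' @export
procedure_spec <- function(id) {
  id <- toupper(id)
  if (!id %in% names(.procedure_table))
    stop("unknown procedure '", id, "' (expected P1..P10)")
  structure(c(list(id = id), .procedure_table[[id]]),
            class = "procedure_spec")
}

# subject-level cleaning: nuisance channels + derivatives + motion
# regressors, optionally band-passed first
clean_timeseries <- function(bundle, config, motion = c("traditional",
                                                        "frame_to_frame")) {
  motion <- match.arg(motion)
  ts <- bundle$ts
  if (config$bandpass)
    ts <- bandpass(ts, bundle$realign$tr_seconds, config$f_lo, config$f_hi)
  mot <- bundle$realign$params
  if (motion == "frame_to_frame") mot <- backward_diff(mot)
  nui <- bundle$nuisance
  X <- cbind(t(nui), backward_diff(t(nui)), mot)
  colnames(X) <- c(paste0("nuis", seq_len(nrow(nui))),
                   paste0("d_nuis", seq_len(nrow(nui))),
                   paste0("mot", 1:6))
  residualize(ts, X, what = "cleaning")
}

#' Apply one motion-correction procedure to one subject
#'
#' Dispatches to the subject-level pipeline of the given procedure and
#' evaluates its eligibility rule. Cohort-level actions (matching, mean-FD
#' covariate) are not applied here; see [procedure_cohort()].
#'
#' @param bundle Subject bundle with `ts` (ROI x time), `realign`
#'   ([realignment_series()]), `nuisance`, and (for DVARS procedures)
#'   `channels`.
#' @param spec A [procedure_spec()] or procedure id string.
#' @param config An [fc_config()].
#' @param distances Canonical edge-distance vector (required for P10).
#' @return List with `matrix` (`connectivity_matrix`), `mask`
#'   ([censor_mask()] or NULL), `eligible`, `fraction_removed`,
#'   `mean_fd_pre`, `mean_fd_post`, `mean_dvars_post`, and for P10 the
#'   fitted `poly` model.
#' @export
apply_procedure <- function(bundle, spec, config = fc_config(),
                            distances = NULL) {
  if (is.character(spec)) spec <- procedure_spec(spec)
  fd <- compute_fd(bundle$realign, radius_mm = config$radius_mm)
  out <- list(id = spec$id, mask = NULL, eligible = TRUE,
              fraction_removed = 0, mean_fd_pre = mean(fd),
              mean_fd_post = mean(fd), mean_dvars_post = NA_real_,
              poly = NULL)
  sid <- bundle$id %||% "subject"
  cm <- switch(
    spec$transform,
    regress6 = correlation_matrix(
      clean_timeseries(bundle, config, "traditional"),
      min_frames = config$min_frames, subject_id = sid),
    regress_ftf = correlation_matrix(
      clean_timeseries(bundle, config, "frame_to_frame"),
      min_frames = config$min_frames, subject_id = sid),
    partial6 = partial_correlation_matrix(
      clean_timeseries(bundle, config, "traditional"),
      covariates = backward_diff(bundle$realign$params),
      min_frames = config$min_frames, subject_id = sid),
    partial_fd = partial_correlation_matrix(
      clean_timeseries(bundle, config, "traditional"),
      covariates = fd,
      min_frames = config$min_frames, subject_id = sid),
    censor_fd = {
      mask <- make_censor_mask(fd, config$fd_threshold,
                               config$frames_before, config$frames_after,
                               source_metric = "fd")
      out$mask <- mask
      correlation_matrix(clean_timeseries(bundle, config, "traditional"),
                         mask = mask, min_frames = config$min_frames,
                         subject_id = sid)
    },
    censor_dvars = {
      if (is.null(bundle$channels))
        stop(spec$id, " requires channel data to compute DVARS; ",
             "the subject bundle has none")
      dv <- compute_dvars(bundle$channels, normalize = TRUE)
      mask <- make_censor_mask(dv, config$dvars_threshold,
                               config$frames_before, config$frames_after,
                               source_metric = "dvars")
      out$mask <- mask
      out$mean_dvars_post <- if (any(mask)) mean(dv[mask]) else NA_real_
      correlation_matrix(clean_timeseries(bundle, config, "traditional"),
                         mask = mask, min_frames = config$min_frames,
                         subject_id = sid)
    },
    poly_correct = {
      if (is.null(distances))
        stop("P10 requires the edge-distance vector")
      mask <- make_censor_mask(fd, config$fd_threshold,
                               config$frames_before, config$frames_after,
                               source_metric = "fd")
      out$mask <- mask
      clean <- clean_timeseries(bundle, config, "traditional")
      orig <- correlation_matrix(clean, min_frames = config$min_frames,
                                 subject_id = sid)
      if (eligibility_ok(fraction_removed(mask), spec$eligibility)) {
        scrub <- correlation_matrix(clean, mask = mask,
                                    min_frames = config$min_frames,
                                    subject_id = sid)
        fit <- fit_polynomial_correction(orig, scrub, distances,
                                         degree = config$poly_degree)
        out$poly <- fit$model
        fit$corrected
      } else {
        orig  # ineligible: no model fit, original carried through
      }
    },
    stop("unhandled transform ", spec$transform)
  )
  if (!is.null(out$mask)) {
    out$fraction_removed <- fraction_removed(out$mask)
    out$mean_fd_post <- if (any(out$mask)) mean(fd[out$mask]) else NA_real_
  }
  out$eligible <- eligibility_ok(out$fraction_removed, spec$eligibility)
  cm$eligible <- cm$eligible && out$eligible
  out$matrix <- cm
  out
}

# eligibility rules; boundaries follow their stated inequalities exactly:
# "<60% of frames removed" is strict, "at least 40% remaining" is not
eligibility_ok <- function(frac_removed, rule) {
  switch(rule,
         none = TRUE,
         lt60_removed = frac_removed < 0.60,
         ge40_remaining = (1 - frac_removed) >= 0.40,
         stop("unknown eligibility rule ", rule))
}

#' Cohort eligibility filter
#'
#' Applies a frame-removal eligibility rule to each subject's censor mask
#' and logs every exclusion.
#'
#' @param ids Subject ids.
#' @param fractions_removed Per-subject fraction of frames removed.
#' @param rule `"none"`, `"lt60_removed"` (retain when < 60% removed), or
#'   `"ge40_remaining"` (retain when >= 40% remain).
#' @return List with logical `retained` (named by id) and a data frame
#'   `log` of excluded subjects and reasons.
#' @export
eligibility_filter <- function(ids, fractions_removed, rule = "none") {
  keep <- vapply(fractions_removed, eligibility_ok, TRUE, rule = rule)
  names(keep) <- ids
  log <- data.frame(id = ids[!keep],
                    fraction_removed = fractions_removed[!keep],
                    reason = if (any(!keep)) paste0("eligibility rule ",
                                                    rule) else character(0),
                    stringsAsFactors = FALSE)
  list(retained = keep, log = log)
}

#' Motion "matching" by greedy subject removal
#'
#' Removes subjects one at a time until the Pearson correlation between a
#' per-subject motion summary (mean FD or mean DVARS) and the target
#' variable (age) is no longer significant at `alpha`. Each step scans
#' every single-subject removal exhaustively and removes the one that
#' most reduces `|r|`; ties are broken by lexicographic subject id, so the
#' result is deterministic. Aborts when more than half the cohort would
#' have to be removed.
#'
#' @param ids Subject ids.
#' @param motion Per-subject motion summary.
#' @param target Variable to decorrelate from motion (age).
#' @param alpha Significance level that keeps the loop running.
#' @return List with `retained` (ids), `removed` (ids in removal order),
#'   `final_r`, `final_p`, `n_removed`.
#' @export
match_subjects <- function(ids, motion, target, alpha = 0.05) {
  stopifnot(length(ids) == length(motion), length(motion) == length(target))
  if (length(ids) < 10) stop("matching needs at least 10 subjects")
  ids <- as.character(ids)
  keep <- seq_along(ids)
  removed <- character(0)
  max_remove <- floor(length(ids) / 2)
  cor_p <- function(idx) {
    ct <- suppressWarnings(stats::cor.test(motion[idx], target[idx]))
    c(r = unname(ct$estimate), p = ct$p.value)
  }
  repeat {
    cur <- cor_p(keep)
    if (is.na(cur["p"]) || cur["p"] >= alpha) break
    if (length(removed) >= max_remove)
      stop(sprintf(paste0("cohort could not be motion-matched: %d of %d ",
                          "subjects removed and motion-%s correlation is ",
                          "still r = %.3f (p = %.2g)"),
                   length(removed), length(ids), "target",
                   cur["r"], cur["p"]))
    cand_r <- vapply(seq_along(keep), function(k) {
      abs(suppressWarnings(stats::cor(motion[keep[-k]], target[keep[-k]])))
    }, 0)
    cand_r[is.na(cand_r)] <- Inf
    best <- order(cand_r, ids[keep])[1]
    removed <- c(removed, ids[keep[best]])
    keep <- keep[-best]
  }
  final <- cor_p(keep)
  list(retained = ids[keep], removed = removed,
       final_r = unname(final["r"]), final_p = unname(final["p"]),
       n_removed = length(removed))
}

#' Distance-polynomial r-value correction
#'
#' Fits, per subject, a polynomial in inter-ROI distance to the
#' censoring-induced change in correlation (`delta r = scrubbed r -
#' original r`) over the valid edges, then corrects the original values by
#' the predicted delta: `corrected = original + poly(distance)`. The
#' corrected matrix approximates the scrubbed estimate without discarding
#' frames. The self-check statistic is the correlation between the
#' residual delta (scrubbed - corrected) and distance, which the
#' correction should drive toward zero.
#'
#' @param original,scrubbed `connectivity_matrix` objects on the same
#'   ROI set (scrubbed computed over censored frames).
#' @param distances Canonical edge-distance vector.
#' @param degree Polynomial degree (fitted with an intercept).
#' @return List with `model` (coefficients, degree, self-check
#'   correlations `precorrection_cor`/`postcorrection_cor`) and
#'   `corrected` (a `connectivity_matrix`; validity flags inherited from
#'   the original).
#' @export
fit_polynomial_correction <- function(original, scrubbed, distances,
                                      degree = 3L) {
  R <- nrow(original$r)
  stopifnot(nrow(scrubbed$r) == R,
            length(distances) == n_edges(R), degree >= 1)
  r0 <- edge_vector(original$r)
  r1 <- edge_vector(scrubbed$r)
  ok <- edge_vector(original$valid) & edge_vector(scrubbed$valid)
  delta <- r1 - r0
  X <- cbind(outer(distances, seq_len(degree), `^`), 1)
  fit <- stats::lm.fit(X[ok, , drop = FALSE], delta[ok])
  coefs <- fit$coefficients
  coefs[is.na(coefs)] <- 0
  pred <- as.numeric(X %*% coefs)
  corr_r <- pmin(1, pmax(-1, r0 + pred))
  cm <- new_connectivity_matrix(edge_to_matrix(corr_r, R, diag = 1),
                                original$n_frames_used,
                                original$subject_id,
                                eligible = original$eligible)
  # correction never changes edge validity
  cm$valid <- original$valid
  cm$z[!cm$valid] <- NA_real_
  pre_cor <- suppressWarnings(stats::cor(delta[ok], distances[ok]))
  resid <- delta - pred
  post_cor <- suppressWarnings(stats::cor(resid[ok], distances[ok]))
  list(model = list(coefficients = coefs, degree = degree,
                    precorrection_cor = pre_cor,
                    postcorrection_cor = post_cor),
       corrected = cm)
}

#' Run one procedure over a whole cohort
#'
#' Applies the subject-level transform to every subject, evaluates
#' eligibility, performs the procedure's cohort-level action (motion
#' matching on the appropriate summary), and assembles the edge-by-subject
#' Fisher-z feature matrix for the retained subjects.
#'
#' @param cohort_obj A `synth_cohort` (or any list with `subjects`,
#'   `cohort`, `distances`).
#' @param proc Procedure id or [procedure_spec()].
#' @param config An [fc_config()].
#' @return List with `z_edges` (edges x retained subjects, NA where
#'   invalid), `retained` (ids), `ages`, `age_covariate` (mean FD vector
#'   for the mean-FD-covariate procedure, else NULL), `results`
#'   (per-subject [apply_procedure()] output), and `report` (matching and
#'   eligibility log).
#' @export
procedure_cohort <- function(cohort_obj, proc, config = fc_config()) {
  spec <- if (is.character(proc)) procedure_spec(proc) else proc
  subjects <- cohort_obj$subjects
  tab <- cohort_obj$cohort
  results <- lapply(subjects, apply_procedure, spec = spec, config = config,
                    distances = cohort_obj$distances)
  ids <- tab$id
  eligible <- vapply(results, `[[`, TRUE, "eligible")
  keep <- eligible
  report <- list(procedure = spec$id,
                 excluded_ineligible = ids[!eligible],
                 matching = NULL)
  if (spec$cohort %in% c("fd_match", "fd_match_post", "dvars_match_post")) {
    summary_vec <- switch(spec$cohort,
      fd_match = vapply(results, `[[`, 0, "mean_fd_pre"),
      fd_match_post = vapply(results, `[[`, 0, "mean_fd_post"),
      dvars_match_post = vapply(results, `[[`, 0, "mean_dvars_post"))
    idx <- which(keep & is.finite(summary_vec))
    m <- match_subjects(ids[idx], summary_vec[idx], tab$age[idx],
                        alpha = config$match_alpha)
    keep[idx] <- ids[idx] %in% m$retained
    report$matching <- m
  }
  z_edges <- vapply(results[keep], function(res) {
    z <- edge_vector(res$matrix$z)
    z[!edge_vector(res$matrix$valid)] <- NA_real_
    z
  }, numeric(n_edges(nrow(cohort_obj$rois))))
  age_cov <- if (spec$cohort == "mean_fd_covariate")
    vapply(results[keep], `[[`, 0, "mean_fd_pre")
  list(z_edges = z_edges, retained = ids[keep], ages = tab$age[keep],
       age_covariate = age_cov, results = results, report = report)
}
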