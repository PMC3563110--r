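# Edge-wise age association, FDR, distance contrasts, and the
# frame-removal degradation simulation.

#' Benjamini-Hochberg FDR significance flags
#'
#' Standard step-up rule: sort the p-values, find the largest k with
#' `p_(k) <= k q / m`, and reject hypotheses 1..k.
#'
#' @param p Finite p-values in `[0, 1]`.
#' @param q FDR level.
#' @return Logical rejection flags, same order as `p`.
#' @export
bh_fdr <- function(p, q = 0.05) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must be finite and within [0, 1]")
  stats::p.adjust(p, method = "BH") <= q
}

#' Edge-wise age association
#'
#' Pearson correlation of each edge's Fisher-z connectivity with subject
#' age, with two-sided p-values, BH-FDR flags at `q`, and the sign of the
#' trend (stronger/weaker with age). With a per-subject covariate (mean
#' FD, the group-level correction) partial correlations are computed as
#' correlations of OLS residuals, and the degrees of freedom drop
#' accordingly. Edges that are invalid for any subject are skipped and
#' flagged.
#'
#' @param z_edges Edges x subjects matrix of Fisher-z values (NA =
#'   invalid edge for that subject).
#' @param ages Subject ages (>= 10 subjects).
#' @param covariate Optional per-subject covariate vector (or matrix,
#'   subjects in rows).
#' @param distances Optional canonical edge-distance vector to attach.
#' @param q FDR level.
#' @return Data frame of class `age_association`: `edge`, `r`, `p`,
#'   `sig`, `sign` (+1 stronger / -1 weaker / NA), `distance`, `skipped`.
#' @export
edge_age_correlation <- function(z_edges, ages, covariate = NULL,
                                 distances = NULL, q = 0.05) {
  z_edges <- as.matrix(z_edges)
  n <- ncol(z_edges)
  if (length(ages) != n)
    stop("ages length does not match the number of subjects")
  if (n < 10) stop("age association needs at least 10 subjects")
  ok <- rowSums(!is.finite(z_edges)) == 0
  Z <- z_edges[ok, , drop = FALSE]
  a <- ages
  k_cov <- 0
  if (!is.null(covariate)) {
    X <- cbind(1, as.matrix(covariate))
    k_cov <- ncol(X) - 1
    q_x <- qr(X)
    a <- qr.resid(q_x, ages)
    Z <- t(qr.resid(q_x, t(Z)))
  }
  ac <- a - mean(a)
  Zc <- Z - rowMeans(Z)
  num <- as.numeric(Zc %*% ac)
  den <- sqrt(rowSums(Zc^2)) * sqrt(sum(ac^2))
  r <- ifelse(den > 0, num / den, NA_real_)
  df <- n - 2 - k_cov
  tstat <- r * sqrt(df / pmax(1e-300, 1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df)
  p[!is.finite(r)] <- NA_real_
  out <- data.frame(edge = seq_len(nrow(z_edges)), r = NA_real_,
                    p = NA_real_, sig = FALSE, sign = NA_real_,
                    distance = if (is.null(distances)) NA_real_
                               else distances,
                    skipped = !ok)
  out$r[ok] <- r
  out$p[ok] <- p
  usable <- ok
  usable[ok] <- is.finite(p)
  out$sig[usable] <- bh_fdr(out$p[usable], q)
  out$sign <- ifelse(out$sig, sign(out$r), NA_real_)
  class(out) <- c("age_association", "data.frame")
  out
}

#' Short/long-range split of significant age associations
#'
#' FDR-significant edges are split by the sign of their age correlation;
#' the Euclidean distances of the two sets are compared with a Welch
#' two-sample t-test. Developmentally, connections that strengthen with
#' age tend to link distant regions while weakening connections are
#' short-range; motion artifact exaggerates this gap.
#'
#' @param assoc An `age_association` with distances attached.
#' @return List with the two distance vectors, `mean_stronger`,
#'   `mean_weaker`, `gap` (stronger minus weaker), `t`, `p`, counts, and
#'   `test_defined`.
#' @export
distance_split <- function(assoc) {
  if (all(is.na(assoc$distance)))
    stop("distance_split needs distances attached to the association")
  stronger <- assoc$distance[which(assoc$sig & assoc$r > 0)]
  weaker <- assoc$distance[which(assoc$sig & assoc$r < 0)]
  test_defined <- length(stronger) >= 2 && length(weaker) >= 2
  tt <- if (test_defined) stats::t.test(stronger, weaker) else NULL
  list(stronger = stronger, weaker = weaker,
       mean_stronger = if (length(stronger)) mean(stronger) else NA_real_,
       mean_weaker = if (length(weaker)) mean(weaker) else NA_real_,
       gap = (if (length(stronger)) mean(stronger) else NA_real_) -
             (if (length(weaker)) mean(weaker) else NA_real_),
       n_stronger = length(stronger), n_weaker = length(weaker),
       t = if (test_defined) unname(tt$statistic) else NA_real_,
       p = if (test_defined) tt$p.value else NA_real_,
       test_defined = test_defined)
}

#' Pick low-motion reference subjects
#'
#' Reference subjects for the frame-removal simulation: runs with at most
#' `max_frac` (default 1%) of frames above the FD threshold.
#'
#' @param fd_list List of per-subject FD series.
#' @param threshold FD threshold (mm).
#' @param max_frac Maximum fraction of supra-threshold frames.
#' @return Integer indices of qualifying subjects.
#' @export
select_low_motion <- function(fd_list, threshold = 0.2, max_frac = 0.01) {
  frac <- vapply(fd_list, function(fd) mean(fd > threshold), 0)
  which(frac <= max_frac)
}

# natural cubic-spline imputation of censored frames, per ROI; frames
# outside the retained range take the nearest retained value (splines do
# not extrapolate reliably)
spline_impute <- function(ts, keep) {
  kept <- which(keep)
  if (length(kept) < 4) stop("spline imputation needs >= 4 retained frames")
  miss <- which(!keep)
  out <- ts
  lo <- min(kept); hi <- max(kept)
  for (r in seq_len(nrow(ts))) {
    sf <- stats::splinefun(kept, ts[r, kept], method = "natural")
    vals <- sf(miss)
    vals[miss < lo] <- ts[r, lo]
    vals[miss > hi] <- ts[r, hi]
    out[r, miss] <- vals
  }
  out
}

#' Frame-removal degradation simulation
#'
#' Quantifies how volume censoring degrades a subject's correlation
#' structure. Each donor censor mask (a real removal pattern from a
#' higher-motion subject) is applied to each low-motion reference series;
#' the degraded matrix is compared with the reference's full-data baseline
#' by matrix distance `1 - r` between the vectorized upper triangles. The
#' `censor` variant recomputes the matrix on the retained frames; the
#' `spline` variant instead imputes the censored frames by natural cubic
#' spline interpolation over time and recomputes on all frames.
#'
#' @param refs List of cleaned ROI x time reference matrices.
#' @param donor_masks List of [censor_mask()]s (or logical keep vectors).
#' @param variant `"censor"`, `"spline"`, or `"both"`.
#' @param min_keep Minimum retained frames for the censor variant.
#' @return Data frame: `ref`, `donor`, `fraction_removed`, `variant`,
#'   `distance` (`1 - r`, in `[0, 2]`).
#' @export
frame_removal_simulation <- function(refs, donor_masks,
                                     variant = c("both", "censor", "spline"),
                                     min_keep = 5L) {
  variant <- match.arg(variant)
  variants <- if (variant == "both") c("censor", "spline") else variant
  rows <- list()
  for (i in seq_along(refs)) {
    ts <- as.matrix(refs[[i]])
    T <- ncol(ts)
    base <- edge_vector(suppressWarnings(stats::cor(t(ts))))
    for (j in seq_along(donor_masks)) {
      keep <- as.logical(donor_masks[[j]])
      if (length(keep) > T) {
        warning(sprintf("donor mask %d longer than reference run; truncated",
                        j))
        keep <- keep[seq_len(T)]
      } else if (length(keep) < T) {
        stop(sprintf("donor mask %d shorter (%d) than reference run (%d)",
                     j, length(keep), T))
      }
      frac <- 1 - mean(keep)
      for (v in variants) {
        dist_val <- NA_real_
        if (v == "censor") {
          if (sum(keep) >= max(3, min_keep)) {
            deg <- edge_vector(suppressWarnings(
              stats::cor(t(ts[, keep, drop = FALSE]))))
            dist_val <- 1 - stats::cor(base, deg, use = "complete.obs")
          }
        } else {
          if (sum(keep) >= 4) {
            imp <- spline_impute(ts, keep)
            deg <- edge_vector(suppressWarnings(stats::cor(t(imp))))
            dist_val <- 1 - stats::cor(base, deg, use = "complete.obs")
          }
        }
        rows[[length(rows) + 1]] <- data.frame(
          ref = i, donor = j, fraction_removed = frac, variant = v,
          distance = dist_val, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
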