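# Synthetic motion-contaminated rs-fcMRI cohorts with planted structure.
#
# The generator emulates, at ROI level, the statistical structure the
# motion-correction procedures are designed to confront: network-block
# covariance with a distance-decaying proximity term, linear age trends on
# designated long-range (strengthening) and short-range (weakening) edges,
# subtype-specific edge offsets, and a spike-like motion process whose
# artifact loads more heavily on proximal ROI pairs and whose per-subject
# propensity correlates negatively with age.

#' Evaluate an expression under a temporary RNG state
#'
#' Sets the seed, runs the expression, and restores the caller's random
#' number generator state, so seeded helpers do not perturb surrounding
#' randomness.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# deterministic per-subject seed stream below 2^31
derive_seed <- function(master, i) {
  as.integer((as.numeric(master) + 104729 * as.numeric(i)) %% 2147483629L)
}

.network_names <- c("default", "cerebellum", "fronto_parietal",
                    "cingulo_opercular", "occipital", "sensorimotor")

#' Synthetic cohort configuration
#'
#' Defaults define the study conditions emulated throughout the package:
#' three diagnostic groups of 52 children (ages 7-14 y), 160 ROIs in six
#' functional networks, 200-frame runs at TR 2.5 s, moderate
#' within-network coupling with a 30 mm proximity term, age trends planted
#' on long-range within-network (strengthening) and short-range
#' between-network (weakening) edges, reduced-connectivity subtype offsets
#' (default network for ADHD-C, fronto-parietal/cerebellum for ADHD-I,
#' sensorimotor for both), and a motion-spike process whose propensity
#' correlates negatively with age.
#'
#' @param n_per_group Named vector of subjects per diagnosis.
#' @param age_range Age range in years.
#' @param n_rois,n_networks ROI-geometry size.
#' @param n_frames,tr_seconds Run length and repetition time.
#' @param rho_within,rho_between Baseline within-/between-network Pearson r.
#' @param proximity_weight,proximity_decay Amplitude (z units) and length
#'   scale (mm) of the distance-decaying covariance term.
#' @param beta_age Age slope in z units/year, applied `+` on the designated
#'   long-range within-network edges and `-` on the designated short-range
#'   between-network edges.
#' @param n_age_edges Edges planted per age-effect direction.
#' @param delta_c,delta_i,delta_sm Subtype edge offsets (z units) on the
#'   default-network, fronto-parietal+cerebellum, and sensorimotor edge
#'   sets (negative = reduced connectivity).
#' @param subject_factor_sd Between-subject edge variability (approximate
#'   per-edge correlation s.d. contributed by low-rank subject factors).
#' @param n_subject_factors Rank of the subject-variability component.
#' @param ar_phi Temporal AR(1) coefficient of the BOLD-like signal.
#' @param spike_rate Baseline per-frame spike (Bernoulli) probability.
#' @param spike_meanlog,spike_sdlog Lognormal distribution of the total
#'   framewise displacement (mm) a spike adds across the 6 parameters.
#' @param rho_age_fd Target correlation between age and per-subject motion
#'   propensity (negative: younger children move more).
#' @param artifact_gain Signal units of artifact per (mm of spike FD)
#'   raised to `artifact_power`.
#' @param artifact_power Exponent of the FD-to-artifact amplitude
#'   relationship (> 1: supra-linear, so large displacements corrupt the
#'   signal disproportionately and linear motion regression cannot fully
#'   remove the artifact).
#' @param artifact_coherence Fraction of artifact-loading variance shared
#'   across spikes and subjects: motion artifact has a stereotyped spatial
#'   topography (the same region pairs are inflated in everyone), which is
#'   what turns an age-correlated motion propensity into a systematic
#'   distance-dependent confound of the age analysis.
#' @param artifact_decay Spatial length scale (mm) of the artifact
#'   loadings; smooth loadings make proximal ROI pairs share artifact.
#' @param drift_sd,rot_drift_sd Per-frame random-walk innovations of the
#'   baseline realignment parameters (mm, radians).
#' @param channels_per_roi Noisy channel replicates per ROI (for DVARS).
#' @param channel_noise_sd Channel noise s.d. (signal units).
#' @param intensity_scale Signal units to raw-intensity conversion
#'   (relative to the nominal 1000 intensity).
#' @param dvars_kick Global intensity change (raw units per mm FD) a spike
#'   imprints on all channels, emulating the signal loss abrupt head
#'   displacement causes in echo-planar images.
#' @param pd_floor,pd_tol Eigenvalue floor and maximum admissible
#'   correlation distortion of the nearest-positive-definite projection.
#' @param seed Master seed.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(n_per_group = c("TDC" = 52, "ADHD-I" = 52,
                                         "ADHD-C" = 52),
                         age_range = c(7, 14),
                         n_rois = 160L, n_networks = 6L,
                         n_frames = 200L, tr_seconds = 2.5,
                         rho_within = 0.30, rho_between = 0.05,
                         proximity_weight = 0.20, proximity_decay = 30,
                         beta_age = 0.025, n_age_edges = 400L,
                         delta_c = -0.12, delta_i = -0.12, delta_sm = -0.08,
                         subject_factor_sd = 0.06, n_subject_factors = 8L,
                         ar_phi = 0.3,
                         spike_rate = 0.05,
                         spike_meanlog = log(0.5), spike_sdlog = 0.4,
                         rho_age_fd = -0.45,
                         artifact_gain = 3.5, artifact_power = 1.5,
                         artifact_coherence = 0,
                         artifact_decay = 40,
                         drift_sd = 0.005, rot_drift_sd = 1e-4,
                         channels_per_roi = 4L, channel_noise_sd = 0.4,
                         intensity_scale = 0.0014, dvars_kick = 12,
                         pd_floor = 1e-4, pd_tol = 0.05,
                         seed = 1L) {
  stopifnot(abs(rho_within) < 1, abs(rho_between) < 1,
            n_frames >= 40, n_rois >= 2, abs(rho_age_fd) < 1)
  cfg <- as.list(environment())
  cfg$n_frames <- as.integer(n_frames)
  cfg$n_rois <- as.integer(n_rois)
  cfg$seed <- as.integer(seed)
  class(cfg) <- "synth_config"
  cfg
}

#' Project a symmetric matrix to the nearest positive-definite correlation
#'
#' Eigenvalues below `floor` are clipped to `floor` and the result is
#' rescaled to unit diagonal. Errors when the projection distorts any
#' correlation by more than `tol`.
#'
#' @param m Symmetric matrix with unit diagonal.
#' @param floor Eigenvalue floor.
#' @param tol Maximum admissible absolute change of any entry.
#' @return Positive-definite correlation matrix.
#' @export
nearest_pd <- function(m, floor = 1e-4, tol = 0.05) {
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= floor) return(m)
  v <- pmax(e$values, floor)
  out <- e$vectors %*% (v * t(e$vectors))
  out <- stats::cov2cor(out)
  dev <- max(abs(out - m))
  if (dev > tol)
    stop(sprintf(paste0("positive-definite projection distorted the target",
                        " correlations by %.3f (tolerance %.3f); min",
                        " eigenvalue was %.4f"),
                 dev, tol, min(e$values)))
  out
}

#' Generate a brain-like ROI geometry
#'
#' ROI centres are drawn uniformly inside a head-sized bounding box
#' (+/-70, +/-100, +/-70 mm). Network labels are assigned by k-means
#' spatial clustering into twice as many clusters as networks, then
#' pairing each cluster with a distant one into a single network: each
#' functional network is locally coherent but distributed across two
#' spatial lobes (as real systems such as the default or fronto-parietal
#' network are), so within-network edges span both short and long ranges.
#' Deterministic under `seed`.
#'
#' @param n_rois Number of ROIs (>= 2).
#' @param n_networks Number of network labels (<= `n_rois`).
#' @param seed Integer seed.
#' @return A `roi_set`.
#' @export
generate_roi_geometry <- function(n_rois = 160L, n_networks = 6L, seed = 1L) {
  if (n_networks > n_rois)
    stop("n_networks must not exceed n_rois")
  with_seed(seed, {
    coords <- cbind(x = stats::runif(n_rois, -70, 70),
                    y = stats::runif(n_rois, -100, 100),
                    z = stats::runif(n_rois, -70, 70))
    k_clusters <- 2L * n_networks
    labels <- if (n_networks == 1) {
      rep(1L, n_rois)
    } else if (n_networks == n_rois) {
      seq_len(n_rois)
    } else if (k_clusters > n_rois - 1) {
      # too few ROIs for the two-lobe scheme: plain spatial clustering
      stats::kmeans(coords, centers = n_networks, nstart = 5,
                    iter.max = 50)$cluster
    } else {
      km <- stats::kmeans(coords, centers = k_clusters, nstart = 5,
                          iter.max = 50)
      # pair each cluster with its farthest unpaired partner
      cd <- as.matrix(stats::dist(km$centers))
      assign <- integer(k_clusters)
      free <- seq_len(k_clusters)
      net <- 0L
      while (length(free) > 1) {
        net <- net + 1L
        a <- free[1]
        b <- free[which.max(cd[a, free])]
        if (b == a) b <- free[2]
        assign[c(a, b)] <- net
        free <- setdiff(free, c(a, b))
      }
      if (length(free) == 1) assign[free] <- max(net, 1L)
      assign[km$cluster]
    }
    labels <- ((labels - 1L) %% n_networks) + 1L
    nets <- rep_len(.network_names, n_networks)
    if (n_networks > length(.network_names))
      nets <- c(.network_names,
                paste0("net", seq_len(n_networks - length(.network_names))))
    roi_set(data.frame(id = sprintf("roi%03d", seq_len(n_rois)),
                       coords, network = nets[labels],
                       stringsAsFactors = FALSE))
  })
}

# baseline Fisher-z edge vector: network blocks + proximity term
base_z_edges <- function(rois, dvec, config) {
  ep <- edge_pairs(nrow(rois))
  same <- rois$network[ep[, 1]] == rois$network[ep[, 2]]
  z <- fisher_z(config$rho_between) +
    same * (fisher_z(config$rho_within) - fisher_z(config$rho_between))
  z + config$proximity_weight * exp(-dvec / config$proximity_decay)
}

# plan of planted edge effects (canonical edge indices): age-strengthening
# edges are sampled from the longer half of within-network edges,
# age-weakening ones from the shorter half of between-network edges
# (deterministic under the config seed)
plan_effects <- function(rois, dvec, config) {
  ep <- edge_pairs(nrow(rois))
  n1 <- rois$network[ep[, 1]]
  n2 <- rois$network[ep[, 2]]
  within <- which(n1 == n2)
  between <- which(n1 != n2)
  long_within <- within[dvec[within] > stats::median(dvec[within])]
  short_between <- between[dvec[between] < stats::median(dvec[between])]
  k <- min(config$n_age_edges, length(long_within), length(short_between))
  pick <- with_seed(derive_seed(config$seed, 999), list(
    plus = sort(sample(long_within, k)),
    minus = sort(sample(short_between, k))))
  age_plus <- pick$plus
  age_minus <- pick$minus
  both_in <- function(nets) which(n1 %in% nets & n2 %in% nets)
  list(age_plus = age_plus, age_minus = age_minus,
       dx_c = both_in("default"),
       dx_i = both_in(c("fronto_parietal", "cerebellum")),
       dx_sm = both_in("sensorimotor"),
       age_ref = mean(config$age_range))
}

# subject-specific target z edge vector (base + planted effects)
subject_target_z <- function(base_z, plan, age, diagnosis, config) {
  z <- base_z
  da <- age - plan$age_ref
  z[plan$age_plus] <- z[plan$age_plus] + config$beta_age * da
  z[plan$age_minus] <- z[plan$age_minus] - config$beta_age * da
  if (diagnosis == "ADHD-C") {
    z[plan$dx_c] <- z[plan$dx_c] + config$delta_c
    z[plan$dx_sm] <- z[plan$dx_sm] + config$delta_sm
  } else if (diagnosis == "ADHD-I") {
    z[plan$dx_i] <- z[plan$dx_i] + config$delta_i
    z[plan$dx_sm] <- z[plan$dx_sm] + config$delta_sm
  }
  z
}

# AR(1)-smooth rows of an innovation matrix; the first frame is drawn at
# the stationary scale so marginal variances stay at 1
ar1_rows <- function(innov, phi) {
  if (phi == 0) return(innov)
  out <- innov
  s <- sqrt(1 - phi^2)
  for (t in seq_len(ncol(out))[-1]) {
    out[, t] <- phi * out[, t - 1] + s * innov[, t]
  }
  out
}

#' Generate one synthetic subject
#'
#' Draws a clean multivariate-normal BOLD-like ROI series from the
#' subject's target covariance (network blocks + proximity + planted
#' age/diagnosis offsets in z space, mapped back to correlations and
#' projected to the nearest positive-definite matrix), AR(1)-smoothed over
#' time, plus a low-rank subject-variability component. Motion spikes add
#' (i) displacement pulses to the 6 realignment parameters and (ii) an
#' artifact component with spatially smooth ROI loadings that inflates
#' proximal-pair correlations and bleeds into the following two frames.
#' Each ROI is expanded to noisy channel replicates carrying an additional
#' global intensity change at spike frames, so DVARS is computable.
#'
#' @param age Age in years (within the configured range).
#' @param diagnosis `"TDC"`, `"ADHD-I"`, or `"ADHD-C"`.
#' @param config A [synth_config()].
#' @param seed Integer seed (bit-identical outputs for equal seeds).
#' @param rois Optional pre-built `roi_set` (built from `config` if NULL).
#' @param spike_rate Per-frame spike probability (defaults to the config
#'   baseline; [generate_cohort()] passes age-linked propensities).
#' @return List with `realign` ([realignment_series()]), `ts` (ROI x time),
#'   `channels` (channel x time), `nuisance` (3 x time), `age`,
#'   `diagnosis`, and `ground_truth` (clean target z matrix, spike frames,
#'   true mean FD, spike rate).
#' @export
generate_subject <- function(age, diagnosis, config = synth_config(),
                             seed = config$seed, rois = NULL,
                             spike_rate = config$spike_rate) {
  if (age < config$age_range[1] || age > config$age_range[2])
    stop(sprintf("age %.2f outside configured range [%g, %g]",
                 age, config$age_range[1], config$age_range[2]))
  if (is.null(rois))
    rois <- generate_roi_geometry(config$n_rois, config$n_networks,
                                  seed = config$seed)
  dvec <- edge_distances(rois)
  plan <- plan_effects(rois, dvec, config)
  base_z <- base_z_edges(rois, dvec, config)
  dmat <- as.matrix(stats::dist(as.matrix(rois[, c("x", "y", "z")])))
  spatial_chol <- t(chol(nearest_pd(exp(-dmat / config$artifact_decay),
                                    floor = config$pd_floor, tol = 1)))
  shared_loading <- with_seed(derive_seed(config$seed, 998),
                              as.numeric(spatial_chol %*%
                                           stats::rnorm(nrow(rois))))
  generate_subject_impl(age, diagnosis, config, seed, rois, dvec, plan,
                        base_z, spatial_chol, spike_rate,
                        shared_loading = shared_loading)
}

# core subject generation; cohort-level inputs precomputed by the caller
generate_subject_impl <- function(age, diagnosis, config, seed, rois, dvec,
                                  plan, base_z, spatial_chol, spike_rate,
                                  subject_id = "subject",
                                  spike_meanlog = config$spike_meanlog,
                                  shared_loading = NULL) {
  R <- nrow(rois)
  T <- config$n_frames
  with_seed(seed, {
    ## clean signal
    zt <- subject_target_z(base_z, plan, age, diagnosis, config)
    Rt <- nearest_pd(edge_to_matrix(fisher_z_inv(zt), R),
                     floor = config$pd_floor, tol = config$pd_tol)
    L <- t(chol(Rt))
    innov <- L %*% matrix(stats::rnorm(R * T), R, T)
    ts <- ar1_rows(innov, config$ar_phi)
    ## low-rank subject variability
    k <- config$n_subject_factors
    fac_scale <- config$subject_factor_sd / sqrt(max(k, 1))
    if (k > 0 && fac_scale > 0) {
      G <- matrix(stats::rnorm(R * k), R, k)
      zeta <- ar1_rows(matrix(stats::rnorm(k * T), k, T), config$ar_phi)
      ts <- ts + sqrt(fac_scale) * G %*% zeta
      sigma_exp <- Rt + fac_scale * tcrossprod(G)
    } else {
      sigma_exp <- Rt
    }
    r_exp <- stats::cov2cor(sigma_exp)
    z_clean <- fisher_z(r_exp)
    diag(z_clean) <- 0
    ## realignment parameters: slow drift + spike pulses
    drift <- cbind(matrix(stats::rnorm(T * 3, sd = config$drift_sd), T, 3),
                   matrix(stats::rnorm(T * 3, sd = config$rot_drift_sd), T, 3))
    params <- apply(drift, 2, cumsum)
    spikes <- which(stats::runif(T) < spike_rate)
    fd_mag <- numeric(T)
    for (t in spikes) {
      mag <- stats::rlnorm(1, spike_meanlog, config$spike_sdlog)
      w <- abs(stats::rnorm(6))
      w <- w / sum(w)
      sgn <- sample(c(-1, 1), 6, replace = TRUE)
      off <- sgn * mag * w
      off[4:6] <- off[4:6] / config$radius_mm %||% 50
      params[t, ] <- params[t, ] + off * c(1, 1, 1, 1, 1, 1)
      fd_mag[t] <- mag
    }
    realign <- realignment_series(params, tr_seconds = config$tr_seconds,
                                  dialect = "generic", run_id = subject_id)
    ## distance-dependent artifact with temporal bleed; every spike gets
    ## its own spatially smooth loading vector, so proximal ROI pairs
    ## share artifact systematically while the global mean component
    ## (later removed by global-signal regression) differs per spike
    if (length(spikes)) {
      coh <- config$artifact_coherence
      fresh <- spatial_chol %*% matrix(stats::rnorm(R * length(spikes)),
                                       R, length(spikes))
      if (is.null(shared_loading)) shared_loading <- numeric(R)
      loadings <- sqrt(coh) * matrix(shared_loading, R, length(spikes)) +
        sqrt(1 - coh) * fresh
      S <- matrix(0, length(spikes), T)
      for (k_s in seq_along(spikes)) {
        t0 <- spikes[k_s]
        amp <- config$artifact_gain * fd_mag[t0]^config$artifact_power
        idx <- t0 + 0:2
        w <- c(1, 0.4, 0.15)[idx <= T]
        S[k_s, idx[idx <= T]] <- amp * w
      }
      ts <- ts + loadings %*% S
    }
    ## channel expansion for DVARS
    cpr <- config$channels_per_roi
    idx <- rep(seq_len(R), each = cpr)
    noise <- matrix(stats::rnorm(length(idx) * T,
                                 sd = config$channel_noise_sd),
                    length(idx), T)
    kick <- config$dvars_kick * fd_mag
    channels <- 1000 + 1000 * config$intensity_scale * (ts[idx, ] + noise) +
      matrix(kick, length(idx), T, byrow = TRUE)
    ## nuisance channels: global / white-matter / ventricle analogs
    global <- colMeans(ts) + stats::rnorm(T, sd = 0.05)
    wm <- ar1_rows(matrix(stats::rnorm(T), 1, T), config$ar_phi)[1, ] +
      0.2 * global
    csf <- ar1_rows(matrix(stats::rnorm(T), 1, T), config$ar_phi)[1, ]
    nuisance <- rbind(global = global, wm = wm, csf = csf)
    list(id = subject_id, age = age, diagnosis = diagnosis,
         realign = realign, ts = ts, channels = channels,
         nuisance = nuisance,
         ground_truth = list(z_clean = z_clean, spike_frames = spikes,
                             true_mean_fd = mean(compute_fd(realign)),
                             spike_rate = spike_rate))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic cohort
#'
#' Ages are drawn uniformly over the configured range; per-subject motion
#' propensity is drawn with the configured (negative) correlation with
#' age, so younger subjects carry more spikes and hence more
#' distance-dependent artifact — the confound the correction procedures
#' must remove.
#'
#' @param config A [synth_config()].
#' @param sites Site labels to assign (round-robin-free, sampled).
#' @return List of class `synth_cohort` with elements `cohort`
#'   (a `cohort_table` including motion summaries), `subjects` (list of
#'   per-subject bundles from [generate_subject()]), `rois`, `distances`
#'   (canonical edge vector), `plan` (planted effect indices), and
#'   `config`.
#' @export
generate_cohort <- function(config = synth_config(),
                            sites = c("siteA", "siteB", "siteC")) {
  rois <- generate_roi_geometry(config$n_rois, config$n_networks,
                                seed = config$seed)
  dvec <- edge_distances(rois)
  plan <- plan_effects(rois, dvec, config)
  base_z <- base_z_edges(rois, dvec, config)
  dmat <- as.matrix(stats::dist(as.matrix(rois[, c("x", "y", "z")])))
  spatial_chol <- t(chol(nearest_pd(exp(-dmat / config$artifact_decay),
                                    floor = config$pd_floor, tol = 1)))
  shared_loading <- with_seed(derive_seed(config$seed, 998),
                              as.numeric(spatial_chol %*%
                                           stats::rnorm(nrow(rois))))
  n <- sum(config$n_per_group)
  groups <- rep(names(config$n_per_group), config$n_per_group)
  meta <- with_seed(config$seed, {
    ages <- stats::runif(n, config$age_range[1], config$age_range[2])
    za <- as.numeric(scale(ages))
    prop <- config$rho_age_fd * za +
      sqrt(1 - config$rho_age_fd^2) * stats::rnorm(n)
    rate <- pmin(0.20, pmax(0.005, config$spike_rate * exp(1.0 * prop)))
    mlog <- config$spike_meanlog + 0.2 * prop
    data.frame(id = sprintf("sub%03d", seq_len(n)), age = ages,
               diagnosis = groups,
               site = sample(sites, n, replace = TRUE),
               sex = sample(c("M", "F"), n, replace = TRUE),
               IQ = round(stats::rnorm(n, 110, 12), 1),
               spike_rate = rate, spike_meanlog = mlog,
               stringsAsFactors = FALSE)
  })
  subjects <- lapply(seq_len(n), function(i) {
    generate_subject_impl(meta$age[i], meta$diagnosis[i], config,
                          seed = derive_seed(config$seed, i), rois, dvec,
                          plan, base_z, spatial_chol, meta$spike_rate[i],
                          subject_id = meta$id[i],
                          spike_meanlog = meta$spike_meanlog[i],
                          shared_loading = shared_loading)
  })
  cfg_fc <- fc_config(radius_mm = config$radius_mm %||% 50)
  mfd <- t(vapply(subjects, function(s) {
    fd <- compute_fd(s$realign)
    mask <- make_censor_mask(fd, cfg_fc$fd_threshold,
                             cfg_fc$frames_before, cfg_fc$frames_after)
    c(pre = mean(fd), post = if (any(mask)) mean(fd[mask]) else NA_real_)
  }, numeric(2)))
  tab <- cohort_table(cbind(meta[, c("id", "age", "diagnosis", "site",
                                     "sex", "IQ")],
                            mean_fd_pre = mfd[, "pre"],
                            mean_fd_post = mfd[, "post"]))
  structure(list(cohort = tab, subjects = subjects, rois = rois,
                 distances = dvec, plan = plan, config = config),
            class = "synth_cohort")
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat(sprintf("<synth_cohort> %d subjects (%s), %d ROIs, %d frames\n",
              nrow(x$cohort),
              paste(sprintf("%s=%d", names(table(x$cohort$diagnosis)),
                            table(x$cohort$diagnosis)), collapse = ", "),
              nrow(x$rois), x$config$n_frames))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits the on-disk layout the readers in this package consume: one
#' realignment file, ROI-by-time series TSV and nuisance TSV per subject,
#' plus `rois.tsv`, `phenotype.csv`, and a `ground_truth.json` with spike
#' frames and planted-effect indices.
#'
#' @param cohort_obj A `synth_cohort`.
#' @param dir Output directory (created if needed).
#' @param write_channels Also write the (large) channel matrices.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort_obj, dir, write_channels = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_roi_table(cohort_obj$rois, file.path(dir, "rois.tsv"))
  write_phenotype(cohort_obj$cohort, file.path(dir, "phenotype.csv"))
  for (s in cohort_obj$subjects) {
    write_realignment(s$realign, file.path(dir, paste0(s$id, "_realign.txt")),
                      dialect = "generic")
    write_timeseries(s$ts, file.path(dir, paste0(s$id, "_ts.tsv")))
    write_timeseries(s$nuisance, file.path(dir, paste0(s$id, "_nuisance.tsv")))
    if (write_channels)
      write_timeseries(s$channels, file.path(dir, paste0(s$id,
                                                         "_channels.tsv")))
  }
  gt <- list(
    plan = lapply(cohort_obj$plan[c("age_plus", "age_minus", "dx_c",
                                    "dx_i", "dx_sm")], as.integer),
    spike_frames = lapply(cohort_obj$subjects,
                          function(s) as.integer(s$ground_truth$spike_frames)),
    true_mean_fd = vapply(cohort_obj$subjects,
                          function(s) s$ground_truth$true_mean_fd, 0)
  )
  names(gt$spike_frames) <- vapply(cohort_obj$subjects, `[[`, "", "id")
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
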