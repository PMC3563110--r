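test_that("ROI geometry is deterministic, labelled, and brain-sized", {
  rois <- generate_roi_geometry(160, 6, seed = 1)
  expect_equal(nrow(rois), 160)
  expect_equal(length(unique(rois$network)), 6)
  expect_true(all(abs(rois$x) <= 70) && all(abs(rois$y) <= 100) &&
                all(abs(rois$z) <= 70))
  expect_identical(rois, generate_roi_geometry(160, 6, seed = 1))

  two <- generate_roi_geometry(2, 1, seed = 3)
  d <- edge_distances(two)
  expect_equal(d, sqrt(sum((as.numeric(two[1, c("x", "y", "z")]) -
                              as.numeric(two[2, c("x", "y", "z")]))^2)))
  expect_error(generate_roi_geometry(4, 5), "exceed")
})

test_that("networks are spatially distributed enough for long-range edges", {
  rois <- generate_roi_geometry(160, 6, seed = 1)
  d <- edge_distances(rois)
  ep <- edge_pairs(160)
  within <- rois$network[ep[, 1]] == rois$network[ep[, 2]]
  # within-network edges must include genuinely long-range pairs
  expect_gt(max(d[within]), 100)
})

test_that("nearest-PD projection fixes mild indefiniteness and errors loudly", {
  set.seed(31)
  m <- diag(6)
  m[upper.tri(m)] <- 0.1
  m <- (m + t(m)) / 2; diag(m) <- 1
  expect_equal(nearest_pd(m), m)  # already PD: untouched
  m2 <- m; m2[1, 2] <- m2[2, 1] <- 0.999; m2[1, 3] <- m2[3, 1] <- 0.999
  m2[2, 3] <- m2[3, 2] <- -0.9   # strongly inconsistent triple
  expect_error(nearest_pd(m2, tol = 0.01), "distorted")
  out <- nearest_pd(m2, tol = 1)
  expect_gt(min(eigen(out, symmetric = TRUE)$values), 0)
  expect_equal(diag(out), rep(1, 6))
})

test_that("subjects are reproducible and motion-free when spikes are off", {
  cfg <- synth_config(n_rois = 12, n_frames = 60, seed = 5)
  rois <- generate_roi_geometry(12, 3, seed = 5)
  a <- generate_subject(10, "TDC", cfg, seed = 100, rois = rois)
  b <- generate_subject(10, "TDC", cfg, seed = 100, rois = rois)
  expect_identical(a$ts, b$ts)
  expect_identical(a$realign$params, b$realign$params)
  expect_identical(a$channels, b$channels)

  quiet <- generate_subject(10, "TDC", cfg, seed = 101, rois = rois,
                            spike_rate = 0)
  fd <- compute_fd(quiet$realign)
  expect_lt(max(fd), 0.2)           # drift only, never near a spike
  expect_length(quiet$ground_truth$spike_frames, 0)

  expect_error(generate_subject(20, "TDC", cfg, seed = 1, rois = rois),
               "outside configured range")
})

test_that("empirical correlations converge to the clean target", {
  # long run, no spikes, no subject factors, no temporal smoothing:
  # sampling error of r at T = 5000 is ~0.014, so nearly all edges land
  # within 0.03 of the target
  cfg <- synth_config(n_rois = 30, n_frames = 5000, spike_rate = 0,
                      subject_factor_sd = 0, ar_phi = 0, seed = 6)
  rois <- generate_roi_geometry(30, 6, seed = 6)
  s <- generate_subject(11, "TDC", cfg, seed = 7, rois = rois)
  emp <- edge_vector(stats::cor(t(s$ts)))
  tgt <- fisher_z_inv(edge_vector(s$ground_truth$z_clean))
  expect_gte(mean(abs(emp - tgt) < 0.03), 0.95)
})

test_that("cohorts have the requested composition and motion-age link", {
  co <- tiny_cohort()
  expect_equal(nrow(co$cohort), 24)
  expect_true(all(co$cohort$diagnosis == "TDC"))
  expect_true(all(co$cohort$age >= 7 & co$cohort$age <= 14))

  co3 <- generate_cohort(synth_config(n_per_group = c("TDC" = 4,
                                                      "ADHD-I" = 4,
                                                      "ADHD-C" = 4),
                                      n_rois = 10, n_frames = 50, seed = 8))
  expect_equal(as.integer(table(co3$cohort$diagnosis)[c("TDC", "ADHD-I",
                                                        "ADHD-C")]),
               rep(4L, 3))

  # requested age-motion correlation is realized within sampling error
  sc <- synth_config(n_per_group = c("TDC" = 150), n_rois = 10,
                     n_frames = 60, rho_age_fd = -0.3, seed = 12)
  cc <- generate_cohort(sc)
  r <- stats::cor(cc$cohort$age, cc$cohort$mean_fd_pre)
  expect_lt(abs(r - (-0.3)), 0.15)
})

test_that("planted age slopes are recoverable from a clean cohort", {
  sc <- synth_config(n_per_group = c("TDC" = 80), n_rois = 60,
                     n_frames = 400, spike_rate = 0,
                     subject_factor_sd = 0, seed = 41)
  co <- generate_cohort(sc)
  Z <- sapply(co$subjects,
              function(s) edge_vector(fisher_z(stats::cor(t(s$ts)))))
  ages <- co$cohort$age
  hits <- vapply(co$plan$age_plus, function(e) {
    f <- stats::lm(Z[e, ] ~ ages)
    est <- stats::coef(f)[2]
    se <- sqrt(diag(stats::vcov(f)))[2]
    abs(est - sc$beta_age) <= 2 * se
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("scrubbing is unbiased when the artifact gain is zero", {
  # spikes present but no artifact: censoring must not shift edge
  # estimates in expectation (paired across seeds)
  diffs <- vapply(1:20, function(s) {
    cfg <- synth_config(n_rois = 15, n_frames = 150, artifact_gain = 0,
                        spike_rate = 0.08, seed = 50 + s)
    rois <- generate_roi_geometry(15, 3, seed = 50)
    sub <- generate_subject(10, "TDC", cfg, seed = 200 + s, rois = rois)
    fd <- compute_fd(sub$realign)
    mask <- make_censor_mask(fd, 0.2)
    if (all(mask) || sum(mask) < 30) return(NA_real_)
    full <- edge_vector(stats::cor(t(sub$ts)))
    scr <- edge_vector(stats::cor(t(sub$ts[, as.logical(mask)])))
    mean(scr - full)
  }, 0)
  diffs <- diffs[is.finite(diffs)]
  expect_gte(length(diffs), 10)
  expect_gt(stats::t.test(diffs)$p.value, 0.01)
})

test_that("the artifact inflates proximal pairs, the premise of scrubbing", {
  co <- tiny_cohort()
  cfg <- fc_config()
  deltas <- lapply(co$subjects, function(s) {
    fd <- compute_fd(s$realign)
    mask <- make_censor_mask(fd, cfg$fd_threshold)
    if (fraction_removed(mask) < 0.05 || sum(mask) < 40) return(NULL)
    full <- edge_vector(stats::cor(t(s$ts)))
    scr <- edge_vector(stats::cor(t(s$ts[, as.logical(mask)])))
    scr - full
  })
  deltas <- deltas[!vapply(deltas, is.null, TRUE)]
  expect_gte(length(deltas), 5)
  md <- rowMeans(do.call(cbind, deltas))
  short <- co$distances < stats::quantile(co$distances, 0.2)
  long <- co$distances > stats::quantile(co$distances, 0.8)
  # scrubbed-minus-original is negative (deflationary) for proximal pairs
  # and clearly below its long-range value
  expect_lt(mean(md[short]), mean(md[long]))
  expect_lt(mean(md[short]), 0)
})
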