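test_that("every procedure id dispatches to exactly one pipeline", {
  ids <- paste0("P", 1:10)
  specs <- lapply(ids, procedure_spec)
  expect_equal(vapply(specs, `[[`, "", "id"), ids)
  expect_setequal(unique(vapply(specs, `[[`, "", "transform")),
                  c("regress6", "partial6", "partial_fd", "regress_ftf",
                    "censor_fd", "censor_dvars", "poly_correct"))
  expect_error(procedure_spec("P11"), "unknown procedure")

  s <- tiny_cohort()$subjects[[1]]
  d <- tiny_cohort()$distances
  cfg <- fc_config()
  for (id in ids) {
    res <- apply_procedure(s, id, cfg, distances = d)
    expect_s3_class(res$matrix, "connectivity_matrix")
  }
})

test_that("censoring procedures reduce to plain correlation without motion", {
  co <- tiny_cohort()
  cfg <- fc_config()
  rois <- generate_roi_geometry(20, 4, seed = 61)
  quiet <- generate_subject(10, "TDC",
                            synth_config(n_rois = 20, n_frames = 500,
                                         seed = 61),
                            seed = 62, rois = rois, spike_rate = 0)
  p1 <- apply_procedure(quiet, "P1", cfg)
  p7 <- apply_procedure(quiet, "P7", cfg)
  # no frames over threshold: identical pipelines
  expect_equal(fraction_removed(p7$mask), 0)
  expect_lt(max(abs(p1$matrix$z - p7$matrix$z), na.rm = TRUE), 0.02)

  s <- co$subjects[[1]]
  s$channels <- NULL
  expect_error(apply_procedure(s, "P9", cfg), "channel data")
})

test_that("motion matching is greedy, deterministic, and bounded", {
  # no initial relationship: identity
  set.seed(63)
  ids <- sprintf("s%02d", 1:12)
  age <- runif(12, 7, 14)
  motion <- rnorm(12, 0.1, 0.01)
  m <- match_subjects(ids, motion, age, alpha = 0.05)
  expect_equal(m$retained, ids)
  expect_equal(m$n_removed, 0)

  # one outlier drives the correlation; the exhaustive scan removes it
  age2 <- c(7, 8, 9, 10, 11, 12, 13, 14, 7.5, 12.5)
  motion2 <- rnorm(10, 0.10, 0.005)
  motion2[1] <- 0.5                      # young + very high motion
  ids2 <- sprintf("t%02d", 1:10)
  if (stats::cor.test(motion2, age2)$p.value < 0.05) {
    m2 <- match_subjects(ids2, motion2, age2)
    expect_equal(m2$removed[1], "t01")
  }
  # verify first removal against exhaustive search
  cand <- vapply(1:10, function(k) abs(stats::cor(motion2[-k], age2[-k])), 0)
  expect_equal(which.min(cand), 1L)

  # perfectly collinear motion and age cannot be matched
  expect_error(match_subjects(sprintf("u%02d", 1:20), seq(0.1, 0.3,
                                                          length.out = 20),
                              seq(7, 14, length.out = 20)),
               "could not be motion-matched")

  # idempotence: rerunning on the matched set removes nobody
  co <- tiny_cohort()
  mm <- match_subjects(co$cohort$id, co$cohort$mean_fd_pre, co$cohort$age,
                       alpha = 0.05)
  keep <- co$cohort$id %in% mm$retained
  mm2 <- match_subjects(co$cohort$id[keep], co$cohort$mean_fd_pre[keep],
                        co$cohort$age[keep], alpha = 0.05)
  expect_equal(mm2$n_removed, 0)
})

test_that("polynomial correction recovers planted distance trends", {
  set.seed(64)
  R <- 20
  r0 <- matrix(0.2, R, R); diag(r0) <- 1
  rois <- generate_roi_geometry(R, 4, seed = 64)
  d <- edge_distances(rois)
  orig <- correlation_matrix(matrix(rnorm(R * 100), R, 100))

  # delta identically zero: all coefficients zero, corrected == original
  fit0 <- fit_polynomial_correction(orig, orig, d, degree = 3)
  expect_lt(max(abs(fit0$model$coefficients)), 1e-10)
  expect_equal(fit0$corrected$r, orig$r, tolerance = 1e-10)

  # planted linear delta recovered exactly from noiseless data
  delta <- 0.1 - 0.001 * d
  scr_r <- edge_to_matrix(edge_vector(orig$r) + delta, R)
  scr <- orig; scr$r <- scr_r; scr$z <- fisher_z(scr_r)
  fit1 <- fit_polynomial_correction(orig, scr, d, degree = 2)
  cf <- fit1$model$coefficients
  expect_equal(unname(cf[3]), 0.1, tolerance = 1e-6)     # intercept (last)
  expect_equal(unname(cf[1]), -0.001, tolerance = 1e-6)  # linear term
  expect_equal(unname(cf[2]), 0, tolerance = 1e-8)
  expect_equal(edge_vector(fit1$corrected$r),
               edge_vector(scr$r), tolerance = 1e-8)

  # correction never changes validity flags
  orig2 <- correlation_matrix(rbind(matrix(rnorm((R - 1) * 100), R - 1,
                                           100), 0))
  fit2 <- fit_polynomial_correction(orig2, orig2, d, degree = 3)
  expect_identical(fit2$corrected$valid, orig2$valid)
})

test_that("the correction drives the delta-distance relationship to zero", {
  co <- tiny_cohort()
  pr <- procedure_cohort(co, "P10", fc_config())
  polys <- Filter(Negate(is.null), lapply(pr$results, `[[`, "poly"))
  polys <- Filter(function(m) is.finite(m$precorrection_cor), polys)
  expect_gt(length(polys), 5)
  reduced <- vapply(polys, function(m)
    abs(m$postcorrection_cor) < abs(m$precorrection_cor), TRUE)
  expect_gte(mean(reduced), 0.95)
})

test_that("eligibility rules use the stated strict/inclusive boundaries", {
  # < 60% removed: 59% retained, 60% excluded
  ef <- eligibility_filter(c("a", "b", "c"), c(0.59, 0.60, 0.61),
                           "lt60_removed")
  expect_equal(unname(ef$retained), c(TRUE, FALSE, FALSE))
  expect_equal(ef$log$id, c("b", "c"))
  # >= 40% remaining: 60% removed is still eligible
  ef2 <- eligibility_filter(c("a", "b"), c(0.60, 0.61), "ge40_remaining")
  expect_equal(unname(ef2$retained), c(TRUE, FALSE))
  # no mask: everyone retained
  ef3 <- eligibility_filter(c("a", "b"), c(0.9, 0.2), "none")
  expect_true(all(ef3$retained))
})

test_that("cohort-level runs assemble feature matrices for retained ids", {
  co <- tiny_cohort()
  pr <- procedure_cohort(co, "P5", fc_config())
  expect_equal(ncol(pr$z_edges), length(pr$retained))
  expect_equal(nrow(pr$z_edges), n_edges(nrow(co$rois)))
  expect_equal(length(pr$age_covariate), length(pr$retained))
  pr7 <- procedure_cohort(co, "P7", fc_config())
  expect_null(pr7$age_covariate)
  expect_true(all(pr7$retained %in% co$cohort$id))
})
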