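test_that("univariate filters rank features like per-feature oracles", {
  set.seed(81)
  n <- 20; p <- 50
  X <- matrix(rnorm(n * p), n, p)
  y <- rnorm(n)
  g2 <- factor(rep(c("A", "B"), each = 10))
  g3 <- factor(rep(c("A", "B", "C"), length.out = n))

  # age mode against per-feature cor.test
  oracle_r <- apply(X, 2, function(v) stats::cor(v, y))
  oracle_p <- apply(X, 2, function(v) stats::cor.test(v, y)$p.value)
  pass <- bh_fdr(oracle_p, 0.9)           # permissive q so some pass
  sel <- univariate_filter(X, y, "age", k = 10, q = 0.9)
  want <- order(-abs(oracle_r), seq_len(p))
  want <- want[pass[want]][seq_len(min(10, sum(pass)))]
  expect_equal(as.integer(sel), want)

  # t-test mode against t.test()
  oracle_t <- apply(X, 2, function(v)
    stats::t.test(v[g2 == "A"], v[g2 == "B"])$statistic)
  sel_t <- univariate_filter(X, g2, "ttest", k = 5)
  expect_equal(as.integer(sel_t),
               order(-abs(oracle_t), seq_len(p))[1:5])

  # anova mode against aov()
  oracle_f <- apply(X, 2, function(v)
    summary(stats::aov(v ~ g3))[[1]]$`F value`[1])
  sel_f <- univariate_filter(X, g3, "anova", k = 5)
  expect_equal(as.integer(sel_f),
               order(-abs(oracle_f), seq_len(p))[1:5])

  # a perfectly correlated feature ranks first
  X2 <- X; X2[, 7] <- y
  expect_equal(as.integer(univariate_filter(X2, y, "age", k = 1,
                                            q = 0.9))[1], 7L)

  # age mode returns only FDR passers when k exceeds them
  sel_all <- univariate_filter(X, y, "age", k = 1000, q = 0.9)
  expect_equal(length(sel_all), sum(pass))
  expect_equal(attr(sel_all, "n_passed"), sum(pass))

  expect_error(univariate_filter(X, y, "age", k = 0), "at least 1")
})

test_that("the sigma-form RBF kernel is PSD and matches the gamma rate", {
  set.seed(82)
  X <- matrix(rnorm(15 * 4), 15, 4)
  sigma <- 2
  K <- exp(-as.matrix(stats::dist(X))^2 / (2 * sigma^2))
  expect_gte(min(eigen(K, symmetric = TRUE)$values), -1e-8)
  # the solver rate parameter reproduces the same kernel values
  K2 <- exp(-fcmotion:::rbf_gamma(sigma) * as.matrix(stats::dist(X))^2)
  expect_equal(K, K2, tolerance = 1e-12)
})

test_that("LOOCV SVR recovers a linear age signal and not noise", {
  set.seed(83)
  n <- 60; p <- 40
  ages <- runif(n, 7, 14)
  X <- matrix(rnorm(n * p, sd = 0.05), n, p)
  X[, 1:5] <- outer(ages, c(0.1, -0.08, 0.05, 0.12, -0.1)) +
    matrix(rnorm(n * 5, sd = 0.01), n, 5)
  fit <- loocv_svr_age(X, ages, svr_config(top_k = 10))
  expect_gt(stats::cor(fit$predicted, ages), 0.95)
  # selection happened strictly per fold
  expect_length(fit$selected, n)

  # constant features: prediction falls back near the training mean
  Xc <- matrix(1, n, p)
  fitc <- loocv_svr_age(Xc, ages, svr_config(top_k = 5))
  expect_lt(max(abs(fitc$predicted - mean(ages))), 2)
})

test_that("held-out subjects cannot influence other folds' selections", {
  set.seed(84)
  n <- 14; p <- 25
  ages <- runif(n, 7, 14)
  X <- matrix(rnorm(n * p), n, p)
  X[, 1:3] <- outer(ages, c(0.2, 0.15, -0.2)) + rnorm(n * 3, sd = 0.05)
  f1 <- loocv_svr_age(X, ages, svr_config(top_k = 5), q = 0.9)
  X2 <- X
  X2[1, ] <- sample(X[1, ])   # corrupt one held-out subject's features
  f2 <- loocv_svr_age(X2, ages, svr_config(top_k = 5), q = 0.9)
  expect_identical(f1$selected[[1]], f2$selected[[1]])
})

test_that("the growth curve fit recovers its parameters", {
  set.seed(85)
  x <- runif(60, 7, 14)
  y <- 20 * (1 - exp(-0.2 * x))
  g <- fit_growth_curve(y, x)
  expect_equal(g$a, 20, tolerance = 1e-6)
  expect_equal(g$b, 0.2, tolerance = 1e-6)
  expect_gt(g$r_squared, 0.999)
  # normalization identity: the curve equals 1 at the maximum age
  expect_equal(g$curve(max(x)) / (g$a * (1 - exp(-g$b * max(x)))), 1)
  expect_equal(g$fcmi, y / g$curve(max(x)), tolerance = 1e-8)

  # noisy recovery at n = 200, 1-year noise
  errs <- vapply(1:20, function(s) {
    set.seed(900 + s)
    xs <- runif(200, 7, 14)
    ys <- 20 * (1 - exp(-0.2 * xs)) + rnorm(200, sd = 1)
    abs(fit_growth_curve(ys, xs)$a - 20) / 20
  }, 0)
  expect_lt(stats::median(errs), 0.1)

  # constant predictions collapse b to the boundary and are flagged
  gc <- fit_growth_curve(rep(10, 20), runif(20, 7, 14))
  expect_true(gc$degenerate)

  expect_error(fit_growth_curve(1:10, c(-1, runif(9, 7, 14))), "positive")
})

test_that("permuted ages leave no recoverable growth signal", {
  set.seed(86)
  n <- 40
  ages <- runif(n, 7, 14)
  X <- matrix(rnorm(n * 30, sd = 0.1), n, 30)
  X[, 1:4] <- outer(ages, rep(0.1, 4)) + rnorm(n * 4, sd = 0.02)
  r2 <- vapply(1:10, function(s) {
    set.seed(1000 + s)
    perm <- sample(ages)
    fit <- loocv_svr_age(X, perm, svr_config(top_k = 5), q = 0.05)
    g <- tryCatch(fit_growth_curve(fit$predicted, perm),
                  error = function(e) NULL)
    if (is.null(g)) 0 else max(0, g$r_squared)
  }, 0)
  expect_lt(stats::median(r2), 0.15)
})

test_that("confound adjustment retains diagnosis and removes nuisances", {
  set.seed(87)
  n <- 40; p <- 15
  dx <- factor(rep(c("TDC", "ADHD-C"), each = n / 2))
  site <- factor(rep(c("s1", "s2"), n / 2))
  sex <- factor(rep(c("M", "M", "F", "F"), n / 4))
  IQ <- rnorm(n, 110, 10)
  # diagnosis-only structure: nuisance coefficients are exactly zero,
  # so adjustment must be the identity
  base <- outer(rep(1, n), rnorm(p)) +
    outer(as.numeric(dx == "ADHD-C"), rnorm(p, sd = 0.5))
  adj0 <- confound_adjust(base, dx, site, sex, IQ)
  expect_equal(unname(adj0), unname(base), tolerance = 1e-10)

  # a planted additive site offset is removed exactly
  shifted <- base + (site == "s2") %o% rep(2, p)
  adj1 <- confound_adjust(shifted, dx, site, sex, IQ)
  expect_equal(unname(adj1), unname(base), tolerance = 1e-10)
  expect_equal(stats::lm(adj1[, 1] ~ site)$coefficients[[2]], 0,
               tolerance = 1e-8)

  # permuting subjects permutes the output identically
  perm <- sample(n)
  adj2 <- confound_adjust(shifted[perm, ], dx[perm], site[perm],
                          sex[perm], IQ[perm])
  expect_equal(unname(adj2), unname(adj1)[perm, ], tolerance = 1e-10)

  expect_error(confound_adjust(base, dx, factor(rep("s1", n)), sex, IQ),
               "rank deficient")
})

test_that("LOOCV SVM separates separable groups and enforces balance", {
  set.seed(88)
  n <- 40
  X <- matrix(rnorm(n * 20, sd = 0.3), n, 20)
  lab <- rep(c("TDC", "ADHD-C"), each = n / 2)
  X[lab == "ADHD-C", 1:5] <- X[lab == "ADHD-C", 1:5] + 3
  rep_ <- loocv_svm_classify(X, lab, svm_config(top_k = 10))
  expect_equal(rep_$accuracy, 1)
  expect_equal(rep_$sensitivity, 1)   # ADHD is the positive class
  expect_equal(rep_$specificity, 1)
  expect_true(all(vapply(rep_$selected,
                         function(s) length(s) == 10, TRUE)))
  # consensus is contained in every fold's selection
  for (s in rep_$selected) expect_true(all(rep_$consensus %in% s))

  expect_error(loocv_svm_classify(X[1:30, ], lab[1:30],
                                  svm_config(top_k = 5)), "unbalanced")
})

test_that("balanced subsampling matches covariates deterministically", {
  co <- generate_cohort(synth_config(n_per_group = c("TDC" = 15,
                                                     "ADHD-I" = 20,
                                                     "ADHD-C" = 28),
                                     n_rois = 10, n_frames = 50,
                                     seed = 89))
  bal <- balance_groups(co$cohort, 12, match_on = c("age", "sex"),
                        seed = 5)
  expect_equal(unname(vapply(bal$ids, length, 1L)), rep(12L, 3))
  bal2 <- balance_groups(co$cohort, 12, match_on = c("age", "sex"),
                         seed = 5)
  expect_identical(bal$ids, bal2$ids)
  # matched groups have closer age means than a worst-case draw
  ages <- split(bal$cohort$age, bal$cohort$diagnosis)
  expect_lt(max(abs(vapply(ages, mean, 0) - mean(bal$cohort$age))), 1.5)

  expect_error(balance_groups(co$cohort, 16), "insufficient")

  # groups already equal with identical covariates: identity subsample
  df <- data.frame(id = sprintf("s%02d", 1:20), age = 10,
                   diagnosis = rep(c("TDC", "ADHD-C"), each = 10),
                   sex = "M", stringsAsFactors = FALSE)
  b2 <- balance_groups(df, 10, match_on = c("age", "sex"), seed = 1)
  expect_setequal(unlist(b2$ids), df$id)
})
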