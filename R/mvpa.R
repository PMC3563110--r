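# SVR-based brain-maturity prediction with growth-curve normalization,
# and LOOCV SVM subtype classification with confound adjustment.

# vectorized per-feature statistics -----------------------------------------

feature_age_cor <- function(X, y) {
  n <- nrow(X)
  yc <- y - mean(y)
  Xc <- sweep(X, 2, colMeans(X))
  num <- as.numeric(crossprod(Xc, yc))
  den <- sqrt(colSums(Xc^2)) * sqrt(sum(yc^2))
  r <- ifelse(den > 0, num / den, 0)
  tstat <- r * sqrt((n - 2) / pmax(1e-300, 1 - r^2))
  list(stat = r, p = 2 * stats::pt(-abs(tstat), n - 2))
}

feature_welch_t <- function(X, g) {
  g <- as.factor(g)
  stopifnot(nlevels(g) == 2)
  i1 <- g == levels(g)[1]
  n1 <- sum(i1); n2 <- sum(!i1)
  m1 <- colMeans(X[i1, , drop = FALSE])
  m2 <- colMeans(X[!i1, , drop = FALSE])
  v1 <- colSums(sweep(X[i1, , drop = FALSE], 2, m1)^2) / (n1 - 1)
  v2 <- colSums(sweep(X[!i1, , drop = FALSE], 2, m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(pmax(se2, 1e-300))
  df <- se2^2 / pmax(v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)),
                     1e-300)
  list(stat = tstat, p = 2 * stats::pt(-abs(tstat), df))
}

feature_anova_f <- function(X, g) {
  g <- as.factor(g)
  k <- nlevels(g)
  n <- nrow(X)
  stopifnot(k >= 2, n > k)
  ind <- stats::model.matrix(~ g - 1)
  ng <- colSums(ind)
  gs <- crossprod(ind, X)                  # k x p group sums
  gm <- gs / ng
  grand <- colMeans(X)
  ssb <- colSums(ng * sweep(gm, 2, grand)^2)
  sst <- colSums(sweep(X, 2, grand)^2)
  ssw <- pmax(sst - ssb, 0)
  f <- (ssb / (k - 1)) / pmax(ssw / (n - k), 1e-300)
  list(stat = f, p = stats::pf(f, k - 1, n - k, lower.tail = FALSE))
}

#' Univariate feature filter
#'
#' Ranks features by the absolute value of a per-feature statistic against
#' the target and returns the indices of the top `k`, ties broken by
#' feature (edge) index. Modes: `"age"` correlates each feature with a
#' continuous target and additionally requires a BH-FDR pass at `q`
#' (features failing FDR are never selected, so fewer than `k` may be
#' returned); `"ttest"` uses the Welch two-sample t statistic;
#' `"anova"` the one-way F statistic. Callers performing cross-validation
#' must apply the filter to training folds only.
#'
#' @param X Subjects x features matrix (training fold).
#' @param y Target: numeric (age mode) or group labels.
#' @param mode `"age"`, `"ttest"`, or `"anova"`.
#' @param k Number of features to keep (>= 1).
#' @param q FDR level (age mode).
#' @return Integer vector of selected feature indices, ranked; attribute
#'   `n_passed` records how many features passed FDR in age mode.
#' @export
univariate_filter <- function(X, y, mode = c("age", "ttest", "anova"),
                              k = 150L, q = 0.05) {
  mode <- match.arg(mode)
  if (k < 1) stop("k must be at least 1")
  X <- as.matrix(X)
  st <- switch(mode,
               age = feature_age_cor(X, y),
               ttest = feature_welch_t(X, y),
               anova = feature_anova_f(X, y))
  score <- abs(st$stat)
  score[!is.finite(score)] <- -Inf
  ord <- order(-score, seq_along(score))
  n_passed <- NA_integer_
  if (mode == "age") {
    pass <- bh_fdr(ifelse(is.finite(st$p), st$p, 1), q)
    n_passed <- sum(pass)
    ord <- ord[pass[ord]]
  }
  sel <- ord[seq_len(min(k, length(ord)))]
  attr(sel, "n_passed") <- n_passed
  sel
}

rbf_svm <- function(x, y, C, sigma, ...) {
  e1071::svm(x = x, y = y, kernel = "radial", gamma = rbf_gamma(sigma),
             cost = C, scale = FALSE, ...)
}

#' Leave-one-out SVR age prediction
#'
#' For each held-out subject, features are re-selected on the remaining
#' subjects (top `top_k` age-correlated, FDR-passing edges) and an
#' epsilon-insensitive RBF support-vector regression is trained on them;
#' feature selection stays strictly inside the loop so the held-out
#' subject never influences it. Folds whose filter returns no feature
#' fall back to the training-mean prediction.
#'
#' @param X Subjects x features matrix (Fisher-z edges, unstandardized).
#' @param ages Chronological ages (>= 10 subjects).
#' @param config An [svr_config()].
#' @param q FDR level for the in-fold filter.
#' @return List with `predicted` (per subject), `selected` (per-fold
#'   feature index sets).
#' @export
loocv_svr_age <- function(X, ages, config = svr_config(), q = 0.05) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 10) stop("LOOCV SVR needs at least 10 subjects")
  stopifnot(length(ages) == n)
  pred <- numeric(n)
  selected <- vector("list", n)
  for (i in seq_len(n)) {
    sel <- univariate_filter(X[-i, , drop = FALSE], ages[-i], "age",
                             k = config$top_k, q = q)
    selected[[i]] <- as.integer(sel)
    if (length(sel) == 0) {
      pred[i] <- mean(ages[-i])
      next
    }
    fit <- rbf_svm(X[-i, sel, drop = FALSE], ages[-i],
                   C = config$C, sigma = config$sigma,
                   type = "eps-regression", epsilon = config$epsilon)
    pred[i] <- stats::predict(fit, X[i, sel, drop = FALSE])
  }
  list(predicted = pred, selected = selected)
}

#' Fit a Von Bertalanffy growth curve and compute fcMI
#'
#' Nonlinear least squares of SVR-predicted age on chronological age under
#' the saturating growth model `a (1 - exp(-b x))`, with five
#' deterministic multi-starts. The functional-connectivity maturity index
#' rescales predictions so the fitted curve equals 1 at the maximum
#' chronological age: `fcMI_i = predicted_i / (a (1 - exp(-b max age)))`.
#'
#' @param predicted SVR-predicted ages.
#' @param chronological Chronological ages (positive, >= 5 subjects).
#' @param level Prediction-limit coverage (default 90%).
#' @return List of class `growth_model`: `a`, `b`, `r_squared`, `fcmi`,
#'   `curve` (function of age), `prediction_limit` (half-width),
#'   `degenerate` (TRUE when b collapsed to the zero boundary).
#' @export
fit_growth_curve <- function(predicted, chronological, level = 0.90) {
  stopifnot(length(predicted) == length(chronological))
  if (length(predicted) < 5) stop("growth fit needs at least 5 subjects")
  if (any(chronological <= 0)) stop("ages must be positive")
  if (stats::sd(predicted) < 1e-10) {
    # constant predictions: the rate parameter collapses to its zero
    # boundary (flagged degenerate; fcMI trivially 1 everywhere)
    return(structure(list(a = mean(predicted), b = 0,
                          r_squared = NA_real_,
                          fcmi = rep(1, length(predicted)),
                          curve = function(x) rep(mean(predicted),
                                                  length(x)),
                          prediction_limit = 0, degenerate = TRUE),
                     class = "growth_model"))
  }
  df <- data.frame(y = predicted, x = chronological)
  a0 <- max(predicted)
  if (!is.finite(a0) || a0 <= 0) a0 <- abs(mean(predicted)) + 1
  starts <- list(c(a = a0, b = 0.1), c(a = 1.5 * a0, b = 0.05),
                 c(a = 0.75 * a0, b = 0.2), c(a = 2 * a0, b = 0.02),
                 c(a = a0, b = 0.5))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a * (1 - exp(-b * x)), data = df,
                        start = as.list(s), lower = c(a = -Inf, b = 1e-9),
                        control = minpack.lm::nls.lm.control(maxiter = 200,
                                                             ftol = 1e-12,
                                                             ptol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      dev <- sum(stats::resid(fit)^2)
      if (is.null(best) || dev < best$dev) best <- list(fit = fit, dev = dev)
    }
  }
  if (is.null(best))
    stop(sprintf(paste0("growth-curve fit failed to converge from 5 starts ",
                        "(n = %d, predicted range %.2f-%.2f)"),
                 length(predicted), min(predicted), max(predicted)))
  cf <- stats::coef(best$fit)
  a <- unname(cf["a"]); b <- unname(cf["b"])
  res <- stats::resid(best$fit)
  r2 <- 1 - sum(res^2) / sum((predicted - mean(predicted))^2)
  top <- a * (1 - exp(-b * max(chronological)))
  fcmi <- if (abs(top) > 1e-12) predicted / top else rep(NA_real_,
                                                         length(predicted))
  halfw <- stats::qt(1 - (1 - level) / 2, length(predicted) - 2) *
    stats::sd(res)
  structure(list(a = a, b = b, r_squared = r2, fcmi = fcmi,
                 curve = function(x) a * (1 - exp(-b * x)),
                 prediction_limit = halfw,
                 degenerate = b <= 1e-8),
            class = "growth_model")
}

#' @export
print.growth_model <- function(x, ...) {
  cat(sprintf("<growth_model> a = %.4f, b = %.4f, R^2 = %.3f%s\n",
              x$a, x$b, x$r_squared,
              if (x$degenerate) " [degenerate: b at zero boundary]" else ""))
  invisible(x)
}

#' Adjust connectivity features for confounding variables
#'
#' Per edge, fits `y = b0 + b1 dx + b2 site + b3 sex + b4 IQ + e` by OLS
#' and returns `b0 + b1 dx + e`: the diagnosis effect is retained while
#' site, sex, and IQ are partialled out.
#'
#' @param X Subjects x features matrix.
#' @param diagnosis Diagnosis factor (retained).
#' @param site,sex Factors (partialled out; site expands to dummies).
#' @param IQ Numeric (partialled out).
#' @return Adjusted subjects x features matrix.
#' @export
confound_adjust <- function(X, diagnosis, site, sex, IQ) {
  X <- as.matrix(X)
  # dummy columns per factor; a single-level factor becomes a constant
  # column so the rank check below names it instead of model.matrix
  # failing opaquely
  fac_cols <- function(v, name) {
    f <- droplevels(factor(v))
    if (nlevels(f) < 2) {
      m <- matrix(1, length(v), 1)
      colnames(m) <- paste0(name, levels(f))
      return(m)
    }
    m <- stats::model.matrix(~f)[, -1, drop = FALSE]
    colnames(m) <- paste0(name, levels(f)[-1])
    m
  }
  dxm <- cbind(`(intercept)` = 1, fac_cols(diagnosis, "diagnosis"))
  nui <- cbind(fac_cols(site, "site"), fac_cols(sex, "sex"), IQ = IQ)
  D <- cbind(dxm, nui)
  q <- qr(D)
  if (q$rank < ncol(D)) {
    dropped <- colnames(D)[q$pivot[(q$rank + 1):ncol(D)]]
    stop("confound design is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  B <- qr.coef(q, X)
  resid <- qr.resid(q, X)
  keep <- seq_len(ncol(dxm))
  out <- D[, keep, drop = FALSE] %*% B[keep, , drop = FALSE] + resid
  dimnames(out) <- dimnames(X)
  out
}

#' Leave-one-out SVM subtype classification
#'
#' Per fold, the top `top_k` group-separating features are re-selected on
#' the training subjects (Welch t-test for two groups, one-way ANOVA for
#' three) and an RBF soft-margin SVM is trained on them. Three-group
#' problems use one-vs-rest binary classifiers with a winner-takes-all
#' rule on the decision values. Groups must be balanced (see
#' [balance_groups()]). Two-group sensitivity/specificity treat the ADHD
#' group as positive.
#'
#' @param X Subjects x features matrix.
#' @param labels Group labels (2 or 3 classes, balanced).
#' @param config An [svm_config()].
#' @return List of class `classification_report`: `accuracy`,
#'   `predicted`, per-class accuracy, `sensitivity`/`specificity`
#'   (2-group), `selected` per fold, `consensus` feature set.
#' @export
loocv_svm_classify <- function(X, labels, config = svm_config()) {
  X <- as.matrix(X)
  labels <- factor(labels)
  n <- nrow(X)
  stopifnot(length(labels) == n)
  counts <- table(labels)
  if (length(counts) < 2 || length(counts) > 3)
    stop("classification supports 2 or 3 groups")
  if (length(unique(counts)) != 1)
    stop("groups are unbalanced (", paste(counts, collapse = "/"),
         "); subsample with balance_groups() first")
  if (min(counts) < 10) stop("need at least 10 subjects per group")
  k3 <- length(counts) == 3
  mode <- if (k3) "anova" else "ttest"
  pred <- character(n)
  selected <- vector("list", n)
  for (i in seq_len(n)) {
    tr_x <- X[-i, , drop = FALSE]
    tr_y <- droplevels(labels[-i])
    sel <- univariate_filter(tr_x, tr_y, mode, k = config$top_k)
    selected[[i]] <- as.integer(sel)
    tr_s <- tr_x[, sel, drop = FALSE]
    te_s <- X[i, sel, drop = FALSE]
    if (!k3) {
      fit <- rbf_svm(tr_s, tr_y, C = config$C, sigma = config$sigma,
                     type = "C-classification")
      pred[i] <- as.character(stats::predict(fit, te_s))
    } else {
      dec <- vapply(levels(labels), function(cl) {
        yb <- factor(ifelse(tr_y == cl, "target", "rest"),
                     levels = c("target", "rest"))
        fit <- rbf_svm(tr_s, yb, C = config$C, sigma = config$sigma,
                       type = "C-classification")
        dv <- attr(stats::predict(fit, te_s, decision.values = TRUE),
                   "decision.values")
        # orient so positive favours the target class
        if (grepl("^target/", colnames(dv)[1])) dv[1, 1] else -dv[1, 1]
      }, 0)
      pred[i] <- names(dec)[which.max(dec)]
    }
  }
  pred <- factor(pred, levels = levels(labels))
  acc <- mean(pred == labels)
  per_class <- vapply(levels(labels),
                      function(cl) mean(pred[labels == cl] == cl), 0)
  sens <- spec <- NA_real_
  if (!k3) {
    pos <- if ("TDC" %in% levels(labels))
      setdiff(levels(labels), "TDC")[1] else levels(labels)[2]
    sens <- mean(pred[labels == pos] == pos)
    neg <- setdiff(levels(labels), pos)[1]
    spec <- mean(pred[labels == neg] == neg)
  }
  structure(list(accuracy = acc, predicted = pred, labels = labels,
                 per_class_accuracy = per_class,
                 sensitivity = sens, specificity = spec,
                 selected = selected,
                 consensus = consensus_features(selected)),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> overall accuracy %.1f%%\n",
              100 * x$accuracy))
  cat("  per class: ",
      paste(sprintf("%s = %.1f%%", names(x$per_class_accuracy),
                    100 * x$per_class_accuracy), collapse = ", "), "\n")
  if (!is.na(x$sensitivity))
    cat(sprintf("  sensitivity %.1f%%, specificity %.1f%%\n",
                100 * x$sensitivity, 100 * x$specificity))
  cat(sprintf("  consensus features: %d\n", length(x$consensus)))
  invisible(x)
}

#' Balanced diagnostic subsampling
#'
#' Draws an equal-size subsample from each diagnostic group, greedily
#' matching the other groups to a reference group on standardized
#' covariates (nearest unused neighbour per reference subject, ties by
#' id), so the classifier is not biased by group size or covariate
#' imbalance. Deterministic under `seed`.
#'
#' @param cohort A `cohort_table` (or data frame with `id`, `diagnosis`,
#'   and the `match_on` columns).
#' @param size Subjects per group.
#' @param match_on Covariate columns to match on (factors are coded
#'   numerically).
#' @param seed Seed for the reference-group draw.
#' @return List with `ids` (selected, per group), `cohort` (subset rows),
#'   `achieved_means` (per group covariate means).
#' @export
balance_groups <- function(cohort, size,
                           match_on = c("age", "sex", "mean_fd_pre"),
                           seed = 1L) {
  df <- as.data.frame(cohort)
  missing_cols <- setdiff(match_on, names(df))
  if (length(missing_cols))
    stop("match_on column(s) not in cohort: ",
         paste(missing_cols, collapse = ", "))
  groups <- split(seq_len(nrow(df)), df$diagnosis)
  groups <- groups[lengths(groups) > 0]
  short <- names(groups)[lengths(groups) < size]
  if (length(short))
    stop("insufficient subjects for size ", size, ": ",
         paste(sprintf("%s has %d", short, lengths(groups)[short]),
               collapse = ", "))
  M <- sapply(match_on, function(cl) {
    v <- df[[cl]]
    if (!is.numeric(v)) v <- as.numeric(as.factor(v))
    v
  })
  M <- scale(M)
  M[is.nan(M)] <- 0
  ref_name <- names(groups)[order(lengths(groups),
                                  names(groups))][1]
  ref_idx <- groups[[ref_name]]
  if (length(ref_idx) > size)
    ref_idx <- with_seed(seed, sort(sample(ref_idx, size)))
  picked <- stats::setNames(vector("list", length(groups)), names(groups))
  picked[[ref_name]] <- ref_idx
  for (g in setdiff(names(groups), ref_name)) {
    avail <- groups[[g]]
    sel <- integer(0)
    for (r in ref_idx) {
      d <- sqrt(colSums((t(M[avail, , drop = FALSE]) - M[r, ])^2))
      best <- avail[order(d, df$id[avail])[1]]
      sel <- c(sel, best)
      avail <- setdiff(avail, best)
    }
    picked[[g]] <- sort(sel)
  }
  idx <- sort(unlist(picked))
  means <- do.call(rbind, lapply(picked, function(ii)
    colMeans(M[ii, , drop = FALSE])))
  list(ids = lapply(picked, function(ii) df$id[ii]),
       cohort = df[idx, , drop = FALSE],
       achieved_means = means)
}
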