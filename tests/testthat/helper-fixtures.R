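# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# small motion-contaminated cohort used by several suites
tiny_cohort <- function() {
  fixture("tiny_cohort", function() {
    generate_cohort(synth_config(n_per_group = c("TDC" = 24),
                                 n_rois = 40, n_frames = 120, seed = 77))
  })
}

# realignment series with a prescribed per-frame parameter matrix
make_series <- function(params, tr = 2.5) {
  realignment_series(params, tr_seconds = tr)
}

# independent brute-force implementations used as oracles ------------------

# literal censoring rule: for each frame over threshold, remove the window
# [i - before, i + after]; union of windows
oracle_censor <- function(metric, threshold, before = 1, after = 2) {
  removed <- integer(0)
  for (i in seq_along(metric)) {
    if (metric[i] > threshold)
      removed <- union(removed, seq(i - before, i + after))
  }
  removed <- removed[removed >= 1 & removed <= length(metric)]
  keep <- rep(TRUE, length(metric))
  keep[removed] <- FALSE
  keep
}

# literal BH step-up
oracle_bh <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- 0
  for (i in seq_len(m)) if (ps[i] <= i * q / m) k <- i
  rej <- rep(FALSE, m)
  if (k > 0) rej[o[seq_len(k)]] <- TRUE
  rej
}

# residual correlation via explicit normal equations
oracle_partial_cor <- function(x, y, Z) {
  Z1 <- cbind(1, Z)
  bx <- solve(t(Z1) %*% Z1, t(Z1) %*% x)
  by <- solve(t(Z1) %*% Z1, t(Z1) %*% y)
  stats::cor(x - Z1 %*% bx, y - Z1 %*% by)
}
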