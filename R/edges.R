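#' Canonical edge ordering for an R-node connectome
#'
#' All edge-indexed quantities in the package (connectivity vectors, distance
#' tables, feature matrices) use a single canonical ordering of the unique
#' off-diagonal pairs of a symmetric matrix: the upper triangle traversed
#' row-major, i.e. (1,2), (1,3), ..., (1,R), (2,3), ..., (R-1,R).
#'
#' @param n_rois Number of nodes (ROIs).
#' @return Integer matrix with `n_rois*(n_rois-1)/2` rows and columns
#'   `i`, `j` (`i < j`), one row per edge in canonical order.
#' @export
#' @examples
#' edge_pairs(4)
edge_pairs <- function(n_rois) {
  n <- as.integer(n_rois)
  stopifnot(n >= 2)
  i <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  j <- sequence((n - 1L):1L, from = 2:n)
  cbind(i = i, j = j)
}

#' Number of unique pairwise connections among n ROIs
#' @param n_rois Number of nodes.
#' @return Integer, `n_rois*(n_rois-1)/2`.
#' @export
n_edges <- function(n_rois) as.integer(n_rois * (n_rois - 1) / 2)

#' Extract the canonical edge vector from a symmetric matrix
#' @param m Symmetric numeric matrix.
#' @return Numeric vector of length `n_edges(nrow(m))` in canonical order.
#' @export
edge_vector <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  m[edge_pairs(nrow(m))]
}

#' Rebuild a symmetric matrix from a canonical edge vector
#' @param v Edge vector in canonical order.
#' @param n_rois Number of nodes.
#' @param diag Value to place on the diagonal (default 1).
#' @return Symmetric `n_rois` x `n_rois` matrix.
#' @export
edge_to_matrix <- function(v, n_rois, diag = 1) {
  ep <- edge_pairs(n_rois)
  stopifnot(length(v) == nrow(ep))
  m <- matrix(0, n_rois, n_rois)
  m[ep] <- v
  m <- m + t(m)
  base::diag(m) <- diag
  m
}

#' Fisher r-to-z transform
#'
#' Variance-stabilizing transform `atanh(r)` applied to correlation
#' coefficients before statistics. Degenerate correlations (`|r| >= 1`)
#' map to +/-Inf and are flagged invalid downstream rather than raising.
#'
#' @param r Correlations in `[-1, 1]`.
#' @return Fisher z values.
#' @export
fisher_z <- function(r) {
  r[r > 1] <- 1
  r[r < -1] <- -1
  atanh(r)
}

#' Inverse Fisher transform
#' @param z Fisher z values.
#' @return Correlations `tanh(z)`.
#' @export
fisher_z_inv <- function(z) tanh(z)
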