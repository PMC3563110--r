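# Node-strength summaries of consensus features and within/between-network
# tabulations.

#' Consensus features across cross-validation folds
#'
#' The intersection of the feature (edge) index sets selected in every
#' fold of a LOOCV procedure: the connections present in each round.
#'
#' @param fold_sets List of integer feature-index vectors (>= 1 fold).
#' @return Sorted integer vector (possibly empty).
#' @export
consensus_features <- function(fold_sets) {
  if (length(fold_sets) < 1) stop("need at least one fold")
  sort(Reduce(intersect, fold_sets))
}

#' Node strength of an edge set
#'
#' The strength of a node is the sum of the absolute weights (z scores)
#' of the edges of interest incident to it; a node with no such edge has
#' strength 0. Satisfies the handshake identity: total strength equals
#' twice the summed absolute edge weights.
#'
#' @param edges Integer edge indices (canonical order, see
#'   [edge_pairs()]).
#' @param weights Per-edge weights aligned with `edges` (finite), e.g.
#'   the group-difference t statistic expressed as a z score, or the
#'   Fisher z of an age correlation.
#' @param rois A `roi_set` defining the nodes.
#' @return Named numeric vector of node strengths (one per ROI).
#' @export
node_strength <- function(edges, weights, rois) {
  stopifnot(length(edges) == length(weights))
  if (length(weights) && any(!is.finite(weights)))
    stop("edge weights must be finite")
  R <- nrow(rois)
  ep <- edge_pairs(R)
  if (length(edges) && (min(edges) < 1 || max(edges) > nrow(ep)))
    stop("edge index outside the ", nrow(ep), "-edge range of this ROI set")
  s <- numeric(R)
  for (k in seq_along(edges)) {
    pr <- ep[edges[k], ]
    s[pr[1]] <- s[pr[1]] + abs(weights[k])
    s[pr[2]] <- s[pr[2]] + abs(weights[k])
  }
  stats::setNames(s, rois$id)
}

#' Within/between-network tabulation of signed age effects
#'
#' Counts FDR-significant connections by whether they strengthen or
#' weaken with age and whether both endpoints share a network label
#' (within) or not (between).
#'
#' @param edges Integer edge indices (canonical order).
#' @param signs Per-edge sign of the age effect (+1 stronger, -1 weaker).
#' @param rois A `roi_set` with network labels.
#' @return 2 x 2 integer matrix, rows `stronger`/`weaker`, columns
#'   `within`/`between`.
#' @export
within_between_tabulation <- function(edges, signs, rois) {
  stopifnot(length(edges) == length(signs))
  if (any(!nzchar(rois$network)) || anyNA(rois$network))
    stop("every ROI needs a non-empty network label")
  ep <- edge_pairs(nrow(rois))
  out <- matrix(0L, 2, 2,
                dimnames = list(c("stronger", "weaker"),
                                c("within", "between")))
  for (k in seq_along(edges)) {
    pr <- ep[edges[k], ]
    within <- rois$network[pr[1]] == rois$network[pr[2]]
    i <- if (signs[k] > 0) 1L else 2L
    j <- if (within) 1L else 2L
    out[i, j] <- out[i, j] + 1L
  }
  out
}
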