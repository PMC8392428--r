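# Baseline binary graph metrics: node degree and clustering coefficient.

#' Node degree of a binary network
#'
#' `D_i = sum_j a_ij`: the number of neighbor nodes of node i (the diagonal
#' is zero by the adjacency invariant, so no self-loops are counted).
#'
#' @param adj binary symmetric adjacency matrix with zero diagonal.
#' @return integer-valued vector of length `nrow(adj)`.
#' @export
nodeDegree <- function(adj) {
  validateAdjacency(adj)
  rowSums(adj)
}

#' Clustering coefficient of a binary network
#'
#' `C_i = 2 E_i / (k_i (k_i - 1))` where `k_i` is the degree of node i and
#' `E_i` the number of edges among its neighbors. Nodes with `k_i <= 1` have
#' no possible neighbor-neighbor edge; their coefficient is defined as 0.
#'
#' E_i is computed algebraically: `2 E_i = (A^3)_ii`, the number of closed
#' triangles through i.
#'
#' @inheritParams nodeDegree
#' @return vector of clustering coefficients in \[0, 1\].
#' @export
clusteringCoef <- function(adj) {
  validateAdjacency(adj)
  k <- rowSums(adj)
  tri <- diag(adj %*% adj %*% adj)  # 2*E_i for each node
  denom <- k * (k - 1)
  ifelse(denom > 0, tri / denom, 0)
}

#' Per-window node-metric feature matrix
#'
#' The baseline feature families used for comparison with tensor features:
#' one length-J node vector per window, stacked into a windows x J matrix.
#'
#' @param adjSeries list of adjacency matrices (one per window).
#' @param metric "degree" or "clustering".
#' @return numeric matrix, one row per window.
#' @export
metricFeatures <- function(adjSeries, metric = c("degree", "clustering")) {
  metric <- match.arg(metric)
  stopifnot(length(adjSeries) > 0)
  f <- if (metric == "degree") nodeDegree else clusteringCoef
  out <- t(vapply(adjSeries, f, numeric(nrow(adjSeries[[1]]))))
  dfnLog("metric features (%s): %d x %d", metric, nrow(out), ncol(out))
  out
}
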