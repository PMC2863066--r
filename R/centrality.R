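#' BaryCenter centrality
#'
#' The sum of a node's shortest-path distances to every node it can reach;
#' central nodes of a component accumulate a *smaller* total than peripheral
#' ones, and an isolated node scores 0. Distances use the same edge-length
#' convention as the kernels ([floyd_warshall()]).
#'
#' @param g an undirected `igraph` graph.
#' @param weight_mode `"unit"` or `"correlation_distance"`.
#' @return Named numeric vector over all nodes.
#' @examples
#' g <- load_graph(data.frame(node_a = c("a", "b"), node_b = c("b", "c")))
#' barycenter_scores(g)  # a 3, b 2, c 3
#' @export
barycenter_scores <- function(g, weight_mode = c("unit", "correlation_distance")) {
  weight_mode <- match.arg(weight_mode)
  D <- floyd_warshall(g, weight_mode)
  fin <- D
  fin[!is.finite(fin)] <- 0
  rowSums(fin)
}

#' Betweenness centrality
#'
#' For each vertex `v`, the sum over unordered pairs of other vertices of
#' the fraction of shortest paths between them that pass through `v`.
#' Weighted graphs use the `1 - weight` edge-length convention.
#'
#' @inheritParams barycenter_scores
#' @return Named numeric vector over all nodes.
#' @examples
#' g <- load_graph(data.frame(node_a = c("a", "b"), node_b = c("b", "c")))
#' betweenness_scores(g)["b"]  # 1
#' @export
betweenness_scores <- function(g, weight_mode = c("unit", "correlation_distance")) {
  weight_mode <- match.arg(weight_mode)
  w <- if (weight_mode == "correlation_distance") {
    if (is.null(igraph::E(g)$weight)) abort("correlation_distance mode needs a weighted graph.")
    1 - igraph::E(g)$weight
  } else {
    NA  # ignore any weight attribute: unit lengths
  }
  b <- igraph::betweenness(g, directed = FALSE, weights = w)
  setNames(as.numeric(b), igraph::V(g)$name)
}

#' Degree centrality
#'
#' The number of connections of each node.
#'
#' @param g an undirected `igraph` graph.
#' @return Named numeric vector over all nodes.
#' @export
degree_scores <- function(g) {
  d <- igraph::degree(g, loops = FALSE)
  setNames(as.numeric(d), igraph::V(g)$name)
}

#' HITS (hubs-and-authorities) centrality
#'
#' Power iteration of the hub/authority mutual-reinforcement updates on the
#' adjacency matrix, each vector L2-normalized per sweep, until the combined
#' L2 change drops below `tol`. The returned score is hub + authority; on an
#' undirected graph the two coincide, so the score is twice the dominant
#' eigenvector of the adjacency matrix (scaled to unit L2 norm).
#'
#' @param g a non-empty undirected `igraph` graph.
#' @param max_iter iteration cap (default 1000).
#' @param tol L2 convergence tolerance (default 1e-8).
#' @return Named numeric vector over all nodes.
#' @export
hits_scores <- function(g, max_iter = 1000, tol = 1e-8) {
  n <- igraph::vcount(g)
  if (n == 0) abort("HITS needs a non-empty graph.")
  A <- .weighted_adjacency(g) > 0  # topology only
  mode(A) <- "numeric"
  l2 <- function(x) sqrt(sum(x^2))
  hub <- auth <- rep(1 / sqrt(n), n)
  for (it in seq_len(max_iter)) {
    auth_new <- as.vector(t(A) %*% hub)
    if (l2(auth_new) > 0) auth_new <- auth_new / l2(auth_new)
    hub_new <- as.vector(A %*% auth_new)
    if (l2(hub_new) > 0) hub_new <- hub_new / l2(hub_new)
    delta <- l2(hub_new - hub) + l2(auth_new - auth)
    hub <- hub_new
    auth <- auth_new
    if (delta < tol) {
      return(setNames(hub + auth, igraph::V(g)$name))
    }
  }
  abort(sprintf("HITS did not converge within %d iterations.", max_iter))
}

#' Cross-graph agreement of a centrality score
#'
#' Normalizes each node's score within its own graph by min-max scaling
#' (removing the magnitude bias between graphs of different size and
#' density) and returns `1 - |difference|`: 1 when the two nodes occupy the
#' same relative position in their respective score ranges, 0 at opposite
#' extremes. When a graph's score range is degenerate (max = min) its
#' normalized score is 0.
#'
#' @param s_u,s_v raw scores of the two nodes in their graphs.
#' @param stats_g1,stats_g2 numeric vectors (or lists) holding the `min` and
#'   `max` of the score over each graph.
#' @return A number in \[0, 1\].
#' @examples
#' pair_score(10, 4, c(min = 0, max = 10), c(min = 0, max = 10))  # 0.4
#' @export
pair_score <- function(s_u, s_v, stats_g1, stats_g2) {
  norm1 <- function(s, st) {
    lo <- unname(st[["min"]])
    hi <- unname(st[["max"]])
    if (hi == lo) 0 else (s - lo) / (hi - lo)
  }
  1 - abs(norm1(s_u, stats_g1) - norm1(s_v, stats_g2))
}
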