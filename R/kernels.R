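#' All-pairs shortest-path distances (Floyd-Warshall)
#'
#' Computes the full distance matrix of a graph by the Floyd-Warshall
#' recurrence. Two edge-length conventions are supported: `"unit"` (every
#' edge has length 1, i.e. hop counts) and `"correlation_distance"` (edge
#' length `1 - weight`, so strongly coexpressed genes are close; requires a
#' weighted graph).
#'
#' @param g an undirected `igraph` graph.
#' @param weight_mode `"unit"` or `"correlation_distance"`.
#' @return A symmetric numeric matrix with zero diagonal, node names as
#'   dimnames, and `Inf` for unreachable pairs.
#' @examples
#' g <- load_graph(data.frame(node_a = c("a", "b"), node_b = c("b", "c")))
#' floyd_warshall(g)["a", "c"]  # 2
#' @export
floyd_warshall <- function(g, weight_mode = c("unit", "correlation_distance")) {
  weight_mode <- match.arg(weight_mode)
  n <- igraph::vcount(g)
  nm <- igraph::V(g)$name
  D <- matrix(Inf, n, n, dimnames = list(nm, nm))
  diag(D) <- 0
  el <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(el) > 0) {
    len <- if (weight_mode == "unit") {
      rep(1, nrow(el))
    } else {
      w <- igraph::E(g)$weight
      if (is.null(w)) abort("correlation_distance mode needs a weighted graph.")
      1 - w
    }
    # parallel edges were collapsed at load time; keep the shorter if any remain
    D[el] <- pmin(D[el], len)
    D[el[, 2:1, drop = FALSE]] <- D[el]
  }
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  }
  D
}

# Attach a hom column in [0, 1]: averaged bitscores min-max normalized over
# every pair of the map, so kernel magnitudes do not track the bitscore
# scale. If all scores coincide (e.g. an identity toy map) every pair gets
# full weight 1. A pre-existing hom column is passed through untouched.
normalize_homology <- function(homology) {
  P <- tibble::as_tibble(homology)
  stopifnot(all(c("node_a", "node_b", "score") %in% names(P)))
  if ("hom" %in% names(P)) return(P)
  if (nrow(P) == 0) {
    P$hom <- numeric(0)
    return(P)
  }
  rng <- range(P$score)
  P$hom <- if (rng[1] == rng[2]) rep(1, nrow(P)) else
    (P$score - rng[1]) / (rng[2] - rng[1])
  P
}

# hom values for pairs within V(C) x V(Z); returns a tibble u, v, hom > 0
.support_pairs <- function(P, nodes_c, nodes_z) {
  P <- normalize_homology(P)
  P <- P[P$node_a %in% nodes_c & P$node_b %in% nodes_z & P$hom > 0, , drop = FALSE]
  tibble::tibble(u = P$node_a, v = P$node_b, hom = P$hom)
}

.infer_weight_mode <- function(C, Z) {
  wC <- isTRUE(igraph::graph_attr(C, "weighted")) || !is.null(igraph::E(C)$weight)
  wZ <- isTRUE(igraph::graph_attr(Z, "weighted")) || !is.null(igraph::E(Z)$weight)
  if (wC && wZ) "correlation_distance" else "unit"
}

#' Homology-weighted shortest-path graph kernel
#'
#' Compares two neighborhoods (typically the k-hop subgraphs around a
#' candidate ortholog pair) by summing, over every ordered vertex pair in
#' each graph connected by a finite shortest path, the product of the
#' endpoint homology weights whenever the two path lengths agree:
#'
#' \deqn{k_{sp}(C,Z) = \sum_{u \ne v} \sum_{u' \ne v'}
#'   hom(u,u')\, hom(v,v')\, \mathbf{1}[\,|d_C(u,v) - d_Z(u',v')| \le
#'   \epsilon\,]}
#'
#' with distances from [floyd_warshall()]. `hom` is the min-max-normalized
#' averaged bitscore (zero for pairs absent from the homology map), so only
#' path pairs whose endpoints are both sequence-homologous contribute. The
#' length-agreement tolerance defaults to 0 for unit lengths and 0.05 for
#' correlation distances.
#'
#' @param C,Z `igraph` neighborhoods from the two species (see
#'   [khop_neighborhood()]).
#' @param homology homology map tibble (`node_a` in C's species, `node_b` in
#'   Z's); an optional `hom` column overrides the built-in normalization.
#' @param weight_mode `"unit"`, `"correlation_distance"`, or `NULL` to infer
#'   from the graphs (weighted pair => correlation distances).
#' @param epsilon length-agreement tolerance; `NULL` for the mode default.
#' @param config an [ortho_config()] supplying the mode defaults.
#' @return A single non-negative number.
#' @export
shortest_path_kernel <- function(C, Z, homology, weight_mode = NULL,
                                 epsilon = NULL, config = ortho_config()) {
  if (is.null(weight_mode)) weight_mode <- .infer_weight_mode(C, Z)
  if (is.null(epsilon)) {
    epsilon <- if (weight_mode == "unit") config$sp_epsilon_unit else
      config$sp_epsilon_weighted
  }
  sup <- .support_pairs(homology, igraph::V(C)$name, igraph::V(Z)$name)
  if (nrow(sup) < 2) return(0)
  DC <- floyd_warshall(C, weight_mode)
  DZ <- floyd_warshall(Z, weight_mode)
  r <- nrow(sup)
  i <- rep(seq_len(r), each = r)   # support pair supplying (u, u')
  j <- rep(seq_len(r), times = r)  # support pair supplying (v, v')
  dC <- DC[cbind(sup$u[i], sup$u[j])]
  dZ <- DZ[cbind(sup$v[i], sup$v[j])]
  ok <- sup$u[i] != sup$u[j] & sup$v[i] != sup$v[j] &
    is.finite(dC) & is.finite(dZ) & abs(dC - dZ) <= epsilon
  sum(sup$hom[i][ok] * sup$hom[j][ok])
}

#' Homology-weighted random-walk graph kernel
#'
#' Counts common walks of the Kronecker product of the two neighborhoods,
#' damped geometrically in walk length and weighted by sequence homology of
#' the vertex pairs visited. The pair-state matrix is
#'
#' \deqn{K[(u,u'),(v,v')] = w_C(u,v)\, w_Z(u',v')\, hom(u,u')\, hom(v,v')}
#'
#' (edge weights `w` are 1 on unweighted graphs and the stored `|rho|` on
#' coexpression graphs), and the kernel value is the grand sum of
#' \eqn{(I - \lambda K)^{-1}}, i.e. \eqn{p (I - \lambda K)^{-1} q} with
#' all-ones `p`, `q` — the Neumann series \eqn{\sum_i \lambda^i p K^i q}.
#' Rows and columns whose vertex pair has zero homology are identity rows of
#' \eqn{I - \lambda K}, so the inverse is evaluated densely on the
#' homology-supported block alone; this is exact, not an approximation.
#'
#' @inheritParams shortest_path_kernel
#' @param lambda walk-damping factor, > 0; must satisfy
#'   `lambda * rho(K) < 1` (spectral radius), default 0.01.
#' @param weight_gate `NULL` for the soft product form of edge-weight
#'   matching (default), or a tolerance `tau`: edges are matched iff both
#'   exist and `|w_C - w_Z| <= tau`, contributing weight 1.
#' @return A single number >= `n*m - |support|`; equals `n*m` when either
#'   neighborhood has no matchable structure.
#' @export
random_walk_kernel <- function(C, Z, homology, lambda = 0.01,
                               weight_gate = NULL, config = ortho_config()) {
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda <= 0) {
    abort("`lambda` must be a positive number.")
  }
  n <- igraph::vcount(C)
  m <- igraph::vcount(Z)
  if (n == 0 || m == 0) {
    warn("Empty neighborhood: random-walk kernel degenerates to n*m.")
    return(n * m)
  }
  sup <- .support_pairs(homology, igraph::V(C)$name, igraph::V(Z)$name)
  r <- nrow(sup)
  if (r == 0) return(n * m)
  AC <- .weighted_adjacency(C)
  AZ <- .weighted_adjacency(Z)
  eC <- AC[cbind(rep(sup$u, each = r), rep(sup$u, times = r))]
  eZ <- AZ[cbind(rep(sup$v, each = r), rep(sup$v, times = r))]
  base <- if (is.null(weight_gate)) eC * eZ else
    as.numeric(eC > 0 & eZ > 0 & abs(eC - eZ) <= weight_gate)
  K <- matrix(base, r, r) * outer(sup$hom, sup$hom)
  spectral_radius <- max(abs(eigen(K, symmetric = TRUE, only.values = TRUE)$values))
  if (lambda * spectral_radius >= 1) {
    abort(sprintf(
      "Random-walk kernel does not converge: lambda * spectral radius = %.4g >= 1 (spectral radius %.4g).",
      lambda * spectral_radius, spectral_radius))
  }
  inv <- solve(diag(r) - lambda * K)
  (n * m - r) + sum(inv)
}

.weighted_adjacency <- function(g) {
  weighted <- !is.null(igraph::E(g)$weight)
  A <- igraph::as_adjacency_matrix(
    g, sparse = FALSE, attr = if (weighted) "weight" else NULL
  )
  nm <- igraph::V(g)$name
  dimnames(A) <- list(nm, nm)
  A
}
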