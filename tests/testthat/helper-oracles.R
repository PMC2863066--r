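# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths (and, where the implementation leans on
# igraph, avoid the same igraph routine).

# random test graph with named vertices; weights drawn in (0.05, 1]
rand_graph <- function(n, p, weighted = FALSE) {
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  if (weighted && igraph::ecount(g) > 0) {
    igraph::E(g)$weight <- round(runif(igraph::ecount(g), 0.05, 1), 3)
  }
  if (weighted) g <- igraph::set_graph_attr(g, "weighted", TRUE)
  g
}

# reachability within k hops by boolean adjacency powers
brute_khop_nodes <- function(g, seed, k) {
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
  nm <- igraph::V(g)$name
  reach <- setNames(nm == seed, nm)
  frontier <- reach
  for (i in seq_len(k)) {
    frontier <- (A %*% frontier) > 0
    reach <- reach | frontier[, 1]
  }
  sort(nm[reach])
}

# all-pairs shortest paths, one Dijkstra per source (independent of the
# Floyd-Warshall implementation under test)
dijkstra_all <- function(g, weight_mode = "unit") {
  w <- if (weight_mode == "unit") NA else 1 - igraph::E(g)$weight
  igraph::distances(g, weights = w, algorithm = if (weight_mode == "unit")
    "unweighted" else "dijkstra")
}

# exhaustive betweenness: enumerate every simple path between each vertex
# pair by DFS, keep the minimal-length ones, count pass-throughs
brute_betweenness <- function(g) {
  nm <- igraph::V(g)$name
  n <- length(nm)
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
  all_paths <- function(s, t) {
    out <- list()
    walk <- function(path) {
      last <- path[length(path)]
      if (last == t) {
        out[[length(out) + 1]] <<- path
        return()
      }
      for (nxt in which(A[last, ])) {
        if (!(nxt %in% path)) walk(c(path, nxt))
      }
    }
    walk(s)
    out
  }
  score <- setNames(numeric(n), nm)
  for (s in 1:(n - 1)) {
    for (t in (s + 1):n) {
      paths <- all_paths(s, t)
      if (length(paths) == 0) next
      lens <- vapply(paths, length, integer(1))
      shortest <- paths[lens == min(lens)]
      sigma <- length(shortest)
      for (v in setdiff(seq_len(n), c(s, t))) {
        through <- sum(vapply(shortest, function(p) v %in% p, logical(1)))
        score[v] <- score[v] + through / sigma
      }
    }
  }
  score
}

# hand min-max normalization of homology scores (mirrors the documented
# convention without calling the package)
oracle_hom <- function(P) {
  rng <- range(P$score)
  h <- if (rng[1] == rng[2]) rep(1, nrow(P)) else
    (P$score - rng[1]) / (rng[2] - rng[1])
  setNames(h, paste(P$node_a, P$node_b))
}

# quadruple-loop shortest-path kernel
sp_kernel_brute <- function(C, Z, P, weight_mode = "unit", epsilon = 0) {
  DC <- dijkstra_all(C, weight_mode)
  DZ <- dijkstra_all(Z, weight_mode)
  hom <- oracle_hom(P)
  h <- function(x, y) {
    v <- unname(hom[paste(x, y)])
    if (is.na(v)) 0 else v
  }
  vc <- igraph::V(C)$name
  vz <- igraph::V(Z)$name
  total <- 0
  for (u in vc) for (v in vc) for (up in vz) for (vp in vz) {
    if (u == v || up == vp) next
    d1 <- DC[u, v]
    d2 <- DZ[up, vp]
    if (!is.finite(d1) || !is.finite(d2) || abs(d1 - d2) > epsilon) next
    total <- total + h(u, up) * h(v, vp)
  }
  total
}

# dense pair-state walk matrix, built entry by entry
rw_kernel_matrix_brute <- function(C, Z, P) {
  hom <- oracle_hom(P)
  h <- function(x, y) {
    v <- unname(hom[paste(x, y)])
    if (is.na(v)) 0 else v
  }
  wC <- igraph::as_adjacency_matrix(
    C, sparse = FALSE,
    attr = if (!is.null(igraph::E(C)$weight)) "weight" else NULL)
  wZ <- igraph::as_adjacency_matrix(
    Z, sparse = FALSE,
    attr = if (!is.null(igraph::E(Z)$weight)) "weight" else NULL)
  vc <- igraph::V(C)$name
  vz <- igraph::V(Z)$name
  rownames(wC) <- colnames(wC) <- vc
  rownames(wZ) <- colnames(wZ) <- vz
  states <- expand.grid(u = vc, up = vz, stringsAsFactors = FALSE)
  r <- nrow(states)
  K <- matrix(0, r, r)
  for (i in seq_len(r)) for (j in seq_len(r)) {
    K[i, j] <- wC[states$u[i], states$u[j]] * wZ[states$up[i], states$up[j]] *
      h(states$u[i], states$up[i]) * h(states$u[j], states$up[j])
  }
  K
}

# truncated Neumann series sum_{i} lambda^i p K^i q
rw_kernel_neumann <- function(C, Z, P, lambda, terms = 80) {
  K <- rw_kernel_matrix_brute(C, Z, P)
  r <- nrow(K)
  vec <- rep(1, r)
  total <- sum(vec)
  for (i in seq_len(terms)) {
    vec <- lambda * (K %*% vec)
    total <- total + sum(vec)
  }
  total
}

# exhaustive positive/negative pair counting AUC (percent)
auc_brute <- function(scores, pos) {
  wins <- 0
  ties <- 0
  for (i in which(pos)) for (j in which(!pos)) {
    if (scores[i] > scores[j]) wins <- wins + 1
    if (scores[i] == scores[j]) ties <- ties + 1
  }
  100 * (wins + ties / 2) / (sum(pos) * sum(!pos))
}

# brute-force reciprocal best hits with lexicographic tie-breaking
rbh_brute <- function(P) {
  out <- list()
  for (a in sort(unique(P$node_a))) {
    rows <- P[P$node_a == a, ]
    rows <- rows[order(-rows$score, rows$node_b), ]
    b <- rows$node_b[1]
    rev_rows <- P[P$node_b == b, ]
    rev_rows <- rev_rows[order(-rev_rows$score, rev_rows$node_a), ]
    if (rev_rows$node_a[1] == a) out[[length(out) + 1]] <- c(a, b)
  }
  if (length(out) == 0) {
    return(tibble::tibble(node_a = character(), node_b = character()))
  }
  m <- do.call(rbind, out)
  tibble::tibble(node_a = m[, 1], node_b = m[, 2])
}

# random sparse homology map between the vertex sets of two graphs
rand_homology <- function(g1, g2, density = 0.3, lo = 50, hi = 900) {
  pairs <- expand.grid(node_a = igraph::V(g1)$name, node_b = igraph::V(g2)$name,
                       stringsAsFactors = FALSE)
  keep <- runif(nrow(pairs)) < density
  tibble::tibble(node_a = pairs$node_a[keep], node_b = pairs$node_b[keep],
                 score = round(runif(sum(keep), lo, hi), 1))
}

# frozen 5-gene toy expression matrix: pairwise Spearman pattern
# (g1,g2)=1.00, (g3,g4)=0.842, (g3,g5)=-0.855, (g1,g4)=0.503,
# (g1,g5)=0.091, every remaining |rho| < 0.68
toy_expression <- function() {
  tibble::tibble(
    gene = paste0("g", 1:5),
    as.data.frame(rbind(
      1:10,
      seq(5, 23, by = 2),
      c(5, 4, 6, 3, 7, 9, 1, 8, 10, 2),
      c(4, 1, 6, 3, 7, 8, 2, 10, 9, 5),
      c(2, 7, 5, 8, 6, 4, 10, 3, 1, 9)
    )) |> setNames(sprintf("t%02d", 1:10))
  )
}
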