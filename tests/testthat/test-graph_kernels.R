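swap_homology <- function(P) {
  tibble::tibble(node_a = P$node_b, node_b = P$node_a, score = P$score)
}

test_that("Floyd-Warshall distances follow both edge-length conventions", {
  path3 <- load_graph(data.frame(node_a = c("a", "b"), node_b = c("b", "c")))
  D <- floyd_warshall(path3)
  expect_equal(D["a", "c"], 2)
  expect_equal(diag(D), setNames(c(0, 0, 0), c("a", "b", "c")))

  pw <- load_graph(data.frame(node_a = c("a", "b"), node_b = c("b", "c"),
                              weight = c(0.9, 0.8)), weighted = TRUE)
  Dw <- floyd_warshall(pw, "correlation_distance")
  expect_equal(Dw["a", "c"], 0.3, tolerance = 1e-12)

  two_comp <- load_graph(data.frame(node_a = c("a", "c"), node_b = c("b", "d")))
  expect_equal(floyd_warshall(two_comp)["a", "d"], Inf)

  expect_error(floyd_warshall(path3, "correlation_distance"), "weighted")
})

test_that("Floyd-Warshall equals per-source Dijkstra on random weighted graphs", {
  set.seed(31)
  for (rep in 1:40) {
    g <- rand_graph(sample(4:15, 1), runif(1, 0.15, 0.5), weighted = TRUE)
    expect_equal(floyd_warshall(g, "correlation_distance"),
                 dijkstra_all(g, "correlation_distance"), tolerance = 1e-10)
    expect_equal(floyd_warshall(g, "unit"), dijkstra_all(g, "unit"))
  }
})

test_that("shortest-path kernel reproduces the hand-computed single-edge case and vanishes without homology", {
  C <- load_graph(data.frame(node_a = "a", node_b = "b"))
  Z <- load_graph(data.frame(node_a = "ap", node_b = "bp"))
  P <- tibble::tibble(node_a = c("a", "b"), node_b = c("ap", "bp"),
                      score = c(1, 1))
  # ordered pairs (a,b)/(ap,bp) and (b,a)/(bp,ap), each contributing 1
  expect_equal(shortest_path_kernel(C, Z, P), 2)

  empty_P <- P[0, ]
  expect_equal(shortest_path_kernel(C, Z, empty_P), 0)

  # self-similarity with identity homology is positive for any graph with an edge
  self_P <- tibble::tibble(node_a = c("a", "b"), node_b = c("a", "b"),
                           score = c(1, 1))
  expect_gt(shortest_path_kernel(C, C, self_P), 0)
})

test_that("shortest-path kernel equals the exhaustive double-sum oracle on random instances", {
  set.seed(41)
  for (rep in 1:30) {
    weighted <- rep %% 2 == 0
    C <- rand_graph(sample(3:8, 1), runif(1, 0.3, 0.7), weighted = weighted)
    Z <- rand_graph(sample(3:8, 1), runif(1, 0.3, 0.7), weighted = weighted)
    igraph::V(Z)$name <- paste0("z", igraph::V(Z)$name)
    P <- rand_homology(C, Z)
    if (nrow(P) == 0) next
    mode <- if (weighted) "correlation_distance" else "unit"
    eps <- if (weighted) 0.05 else 0
    expect_equal(
      shortest_path_kernel(C, Z, P, weight_mode = mode, epsilon = eps),
      sp_kernel_brute(C, Z, P, weight_mode = mode, epsilon = eps),
      tolerance = 1e-12
    )
  }
})

test_that("random-walk kernel: edgeless neighborhoods give n*m and the 4x4 case matches its closed form", {
  C <- igraph::make_empty_graph(n = 2, directed = FALSE)
  igraph::V(C)$name <- c("a", "b")
  Z <- igraph::make_empty_graph(n = 3, directed = FALSE)
  igraph::V(Z)$name <- c("x", "y", "z")
  P <- tibble::tibble(node_a = "a", node_b = "x", score = 1)
  expect_equal(random_walk_kernel(C, Z, P), 6)

  # identical single-edge graphs, identity homology: the 2 supported
  # pair-states form K = [[0,1],[1,0]], so the grand sum of (I - lambda K)^-1
  # is 2/(1 - lambda), plus 2 unsupported states
  C1 <- load_graph(data.frame(node_a = "a", node_b = "b"))
  Z1 <- load_graph(data.frame(node_a = "ap", node_b = "bp"))
  P1 <- tibble::tibble(node_a = c("a", "b"), node_b = c("ap", "bp"),
                       score = c(1, 1))
  lam <- 0.01
  expect_equal(random_walk_kernel(C1, Z1, P1, lambda = lam),
               2 + 2 / (1 - lam), tolerance = 1e-12)
})

test_that("random-walk kernel matches the truncated Neumann series on random instances", {
  set.seed(51)
  for (rep in 1:30) {
    weighted <- rep %% 3 == 0
    C <- rand_graph(sample(3:8, 1), runif(1, 0.3, 0.7), weighted = weighted)
    Z <- rand_graph(sample(3:8, 1), runif(1, 0.3, 0.7), weighted = weighted)
    igraph::V(Z)$name <- paste0("z", igraph::V(Z)$name)
    P <- rand_homology(C, Z)
    if (nrow(P) == 0) next
    K <- rw_kernel_matrix_brute(C, Z, P)
    rho <- max(abs(eigen(K, only.values = TRUE)$values))
    lam <- if (rho > 0) min(0.01, 0.25 / rho) else 0.01
    expect_equal(random_walk_kernel(C, Z, P, lambda = lam),
                 rw_kernel_neumann(C, Z, P, lam), tolerance = 1e-9)
  }
})

test_that("both kernels are symmetric under swapping the two species", {
  set.seed(61)
  for (rep in 1:15) {
    C <- rand_graph(sample(3:8, 1), 0.5)
    Z <- rand_graph(sample(3:8, 1), 0.5)
    igraph::V(Z)$name <- paste0("z", igraph::V(Z)$name)
    P <- rand_homology(C, Z)
    if (nrow(P) == 0) next
    expect_equal(shortest_path_kernel(C, Z, P),
                 shortest_path_kernel(Z, C, swap_homology(P)), tolerance = 1e-12)
    expect_equal(random_walk_kernel(C, Z, P),
                 random_walk_kernel(Z, C, swap_homology(P)), tolerance = 1e-10)
  }
})

test_that("random-walk kernel never decreases in lambda and reports non-convergence", {
  set.seed(71)
  C <- rand_graph(6, 0.6)
  Z <- rand_graph(6, 0.6)
  igraph::V(Z)$name <- paste0("z", igraph::V(Z)$name)
  P <- rand_homology(C, Z, density = 0.5)
  K <- rw_kernel_matrix_brute(C, Z, P)
  rho <- max(abs(eigen(K, only.values = TRUE)$values))
  lams <- seq(0.1, 0.9, by = 0.2) / rho
  vals <- vapply(lams, function(l) random_walk_kernel(C, Z, P, lambda = l),
                 numeric(1))
  expect_true(all(diff(vals) >= 0))
  expect_error(random_walk_kernel(C, Z, P, lambda = 1.5 / rho),
               "spectral radius")
})
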