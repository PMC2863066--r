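#' Load an undirected species network from an edge list
#'
#' Reads a tab-separated edge list (`node_a<TAB>node_b[<TAB>weight]`, comment
#' lines starting with `#`) or takes an equivalent data frame, and returns a
#' canonical undirected [igraph][igraph::igraph-package] graph: duplicate
#' edges are collapsed keeping the maximum weight, self-loops are dropped
#' (the node itself is kept) with a warning.
#'
#' Protein-protein interaction networks are unweighted; gene-coexpression
#' networks carry an edge weight equal to the absolute Spearman correlation,
#' which must lie in (0, 1].
#'
#' @param edges a file path or a data frame with columns `node_a`, `node_b`
#'   and, when `weighted = TRUE`, `weight`.
#' @param weighted logical; does the edge list carry a weight column?
#' @param species_tag label stored on the graph identifying the species.
#' @param header logical; does the file start with a header row?
#'
#' @return An undirected `igraph` object with vertex names, a `species_tag`
#'   graph attribute, and (if weighted) an edge attribute `weight`.
#'
#' @examples
#' el <- data.frame(node_a = c("a", "b", "a"), node_b = c("b", "c", "b"))
#' g <- load_graph(el, species_tag = "toy")
#' igraph::ecount(g)  # duplicate a-b collapsed: 2 edges
#' @export
load_graph <- function(edges, weighted = FALSE, species_tag = "species", header = FALSE) {
  if (is.character(edges) && length(edges) == 1) {
    ncol_expected <- if (weighted) 3L else 2L
    raw <- readr::read_tsv(
      edges,
      col_names = FALSE, comment = "#", skip = if (header) 1L else 0L,
      col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE
    )
    if (nrow(raw) > 0 && ncol(raw) < ncol_expected) {
      abort(sprintf("Edge list '%s' has %d column(s); %d expected.",
                    edges, ncol(raw), ncol_expected))
    }
    bad_weight <- if (weighted && ncol(raw) >= 3) {
      is.na(suppressWarnings(as.numeric(raw[[3]])))
    } else {
      rep(FALSE, nrow(raw))
    }
    bad <- which(is.na(raw[[1]]) | is.na(raw[[2]]) | bad_weight)
    if (length(bad) > 0) {
      abort(sprintf("Malformed edge list line %d in '%s'.",
                    bad[1] + if (header) 1L else 0L, edges))
    }
    edges <- tibble::tibble(node_a = raw[[1]], node_b = raw[[2]])
    if (weighted) edges$weight <- as.numeric(raw[[3]])
  }
  edges <- tibble::as_tibble(edges)
  if (ncol(edges) < 2) abort("Edge table needs at least two columns.")
  names(edges)[1:2] <- c("node_a", "node_b")
  if (weighted) {
    if (ncol(edges) < 3) abort("weighted = TRUE but no weight column present.")
    names(edges)[3] <- "weight"
    edges$weight <- as.numeric(edges$weight)
    if (any(!is.finite(edges$weight) | edges$weight <= 0 | edges$weight > 1)) {
      abort("Edge weights must lie in (0, 1] (absolute correlations).")
    }
  }
  edges$node_a <- as.character(edges$node_a)
  edges$node_b <- as.character(edges$node_b)

  all_nodes <- sort(unique(c(edges$node_a, edges$node_b)))
  loops <- edges$node_a == edges$node_b
  if (any(loops)) {
    warn(sprintf("Dropped %d self-loop(s); nodes retained.", sum(loops)))
    edges <- edges[!loops, , drop = FALSE]
  }
  if (nrow(edges) > 0) {
    u <- pmin(edges$node_a, edges$node_b)
    v <- pmax(edges$node_a, edges$node_b)
    edges$node_a <- u
    edges$node_b <- v
    edges <- edges |>
      dplyr::group_by(.data$node_a, .data$node_b) |>
      dplyr::summarise(
        weight = if (weighted) max(.data$weight) else NA_real_,
        .groups = "drop"
      )
  }
  g <- igraph::graph_from_data_frame(
    d = edges[, c("node_a", "node_b", if (weighted) "weight")],
    directed = FALSE,
    vertices = data.frame(name = all_nodes, stringsAsFactors = FALSE)
  )
  g <- igraph::set_graph_attr(g, "species_tag", species_tag)
  g <- igraph::set_graph_attr(g, "weighted", isTRUE(weighted))
  g
}

#' Extract the k-hop neighborhood around a seed vertex
#'
#' The k-hop neighborhood of a vertex is the subgraph induced by all vertices
#' reachable from it within `k` hops. Hops are topological: edge weights play
#' no role in reachability (they only enter distance and kernel
#' computations). Induced semantics: every edge of the parent graph joining
#' two retained vertices is kept, including edges between two frontier
#' vertices.
#'
#' @param g an undirected `igraph` graph (see [load_graph()]).
#' @param seed vertex name present in `g`.
#' @param k positive integer hop radius.
#'
#' @return An `igraph` subgraph carrying graph attributes `seed` and `k`
#'   (weights and `species_tag` are inherited).
#' @examples
#' g <- load_graph(data.frame(node_a = c("a", "b", "c"),
#'                            node_b = c("b", "c", "d")))
#' igraph::V(khop_neighborhood(g, "a", 2))$name  # a, b, c
#' @export
khop_neighborhood <- function(g, seed, k) {
  stopifnot(igraph::is_igraph(g))
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != as.integer(k)) {
    abort("`k` must be a positive integer.")
  }
  if (!(seed %in% igraph::V(g)$name)) {
    abort(sprintf("Seed vertex '%s' is not in the graph.", seed))
  }
  keep <- igraph::ego(g, order = k, nodes = seed, mode = "all")[[1]]
  sub <- igraph::induced_subgraph(g, keep)
  sub <- igraph::set_graph_attr(sub, "seed", seed)
  sub <- igraph::set_graph_attr(sub, "k", as.integer(k))
  sub
}

#' Candidate cross-species matches for a vertex
#'
#' Looks up, in a homology map (see [average_bidirectional()]), every vertex
#' of the second species matched by BLAST to `vertex` in the first species.
#'
#' @param homology a homology-map tibble with columns `node_a`, `node_b`,
#'   `score`.
#' @param vertex vertex name in the first species' graph.
#' @return Character vector of matched second-species vertex names, sorted;
#'   empty if none.
#' @examples
#' P <- tibble::tibble(node_a = c("v3", "v3"), node_b = c("v'6", "v'2"),
#'                     score = c(100, 250))
#' candidate_matches(P, "v3")
#' @export
candidate_matches <- function(homology, vertex) {
  stopifnot(is.data.frame(homology))
  sort(unique(homology$node_b[homology$node_a == vertex]))
}
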