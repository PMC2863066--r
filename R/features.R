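# Shared per-network-pair context: normalized homology, centrality scores
# with their per-graph ranges, inferred weight mode, and a neighborhood
# cache so each node's k-hop subgraph is extracted once per k.
.pair_context <- function(g1, g2, homology, config = ortho_config()) {
  P <- normalize_homology(homology)
  weight_mode <- .infer_weight_mode(g1, g2)
  cent <- function(g) {
    list(
      barycenter  = barycenter_scores(g, weight_mode),
      betweenness = betweenness_scores(g, weight_mode),
      degree      = degree_scores(g),
      hits        = hits_scores(g, config$hits_max_iter, config$hits_tol)
    )
  }
  with_stats <- function(scores) {
    lapply(scores, function(s) list(s = s, stats = c(min = min(s), max = max(s))))
  }
  list(
    P = P, weight_mode = weight_mode, config = config,
    g1 = g1, g2 = g2,
    c1 = with_stats(cent(g1)), c2 = with_stats(cent(g2)),
    hood1 = new.env(parent = emptyenv()), hood2 = new.env(parent = emptyenv())
  )
}

.cached_hood <- function(ctx, side, node, k) {
  cache <- if (side == 1) ctx$hood1 else ctx$hood2
  key <- paste0(k, "|", node)
  if (is.null(cache[[key]])) {
    g <- if (side == 1) ctx$g1 else ctx$g2
    cache[[key]] <- khop_neighborhood(g, node, k)
  }
  cache[[key]]
}

.feature_row <- function(ctx, u, v) {
  P <- ctx$P
  hit <- which(P$node_a == u & P$node_b == v)
  if (length(hit) == 0) {
    abort(sprintf("Pair (%s, %s) is not in the homology map.", u, v))
  }
  cfg <- ctx$config
  kern <- lapply(cfg$k_hops, function(k) {
    C <- .cached_hood(ctx, 1, u, k)
    Z <- .cached_hood(ctx, 2, v, k)
    list(
      rw = random_walk_kernel(C, Z, P, lambda = cfg$lambda,
                              weight_gate = cfg$rw_weight_gate, config = cfg),
      sp = shortest_path_kernel(C, Z, P, weight_mode = ctx$weight_mode,
                                config = cfg)
    )
  })
  cscore <- function(name) {
    pair_score(ctx$c1[[name]]$s[[u]], ctx$c2[[name]]$s[[v]],
               ctx$c1[[name]]$stats, ctx$c2[[name]]$stats)
  }
  tibble::tibble(
    node_a = u, node_b = v,
    blast = P$score[hit[1]],
    rw1 = kern[[1]]$rw, sp1 = kern[[1]]$sp,
    rw2 = kern[[2]]$rw, sp2 = kern[[2]]$sp,
    barycenter = cscore("barycenter"),
    betweenness = cscore("betweenness"),
    degree = cscore("degree"),
    hits = cscore("hits")
  )
}

#' Feature vector for one candidate ortholog pair
#'
#' Computes the 9 features describing a BLAST-matched pair: the averaged
#' bitscore, the random-walk and shortest-path kernels between the pair's
#' 1-hop and 2-hop neighborhoods, and the cross-graph agreement
#' ([pair_score()]) of the BaryCenter, betweenness, degree and HITS
#' centralities (computed on the whole graphs).
#'
#' @param u,v node names in `g1` and `g2`; the pair must be in the homology
#'   map.
#' @param g1,g2 the two species networks (`igraph`).
#' @param homology homology map from [average_bidirectional()].
#' @param config an [ortho_config()].
#' @return A one-row tibble with columns `node_a`, `node_b`, `blast`, `rw1`,
#'   `sp1`, `rw2`, `sp2`, `barycenter`, `betweenness`, `degree`, `hits`.
#' @export
feature_vector <- function(u, v, g1, g2, homology, config = ortho_config()) {
  ctx <- .pair_context(g1, g2, homology, config)
  .feature_row(ctx, u, v)
}

#' Labeled feature table for every candidate pair
#'
#' Scores every pair of the homology map (the BLAST-filtered candidate
#' universe — non-homologous pairs are never scored) with [feature_vector()]
#' and labels it `ortholog` when it appears in the reference pair set,
#' `non-ortholog` otherwise. Rows are emitted in sorted pair order, so the
#' table is bit-for-bit reproducible.
#'
#' @inheritParams feature_vector
#' @param labels a data frame of known ortholog pairs (columns `node_a`,
#'   `node_b`), e.g. derived from curated orthology groups.
#' @return A tibble: one row per homology-map pair, feature columns as in
#'   [feature_vector()], plus a `label` factor with levels `non-ortholog`,
#'   `ortholog`.
#' @export
feature_table <- function(g1, g2, homology, labels, config = ortho_config()) {
  ctx <- .pair_context(g1, g2, homology, config)
  P <- ctx$P
  if (nrow(P) == 0) {
    warn("Empty homology map: empty feature table.")
  }
  P <- dplyr::arrange(P, .data$node_a, .data$node_b)
  rows <- purrr::map2(P$node_a, P$node_b, function(u, v) .feature_row(ctx, u, v))
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      node_a = character(), node_b = character(), blast = numeric(),
      rw1 = numeric(), sp1 = numeric(), rw2 = numeric(), sp2 = numeric(),
      barycenter = numeric(), betweenness = numeric(), degree = numeric(),
      hits = numeric()
    )
  }
  labels <- tibble::as_tibble(labels)
  pos_key <- character(0)
  if (nrow(labels) > 0) {
    pos_key <- paste(labels$node_a, labels$node_b, sep = "\r")
  }
  out$label <- factor(
    ifelse(paste(out$node_a, out$node_b, sep = "\r") %in% pos_key,
           "ortholog", "non-ortholog"),
    levels = c("non-ortholog", "ortholog")
  )
  out
}

#' Feature names used by the classifiers
#' @return Character vector of the 9 feature column names.
#' @export
ortho_features <- function() {
  c("blast", "rw1", "sp1", "rw2", "sp2",
    "barycenter", "betweenness", "degree", "hits")
}
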