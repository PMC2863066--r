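#' Generate a pair of networks with planted orthologs
#'
#' Simulates the inputs of the whole pipeline for one species pair: a random
#' network for species A, a copy of it for species B in which each edge is
#' independently rewired with probability `rewire_rate` (emulating
#' interactome divergence), a homology map holding high averaged
#' "bitscores" for a planted fraction of corresponding node pairs (the true
#' orthologs, which are also returned as labels) and lower scores for decoy
#' pairs between non-corresponding nodes (spurious sequence similarity).
#'
#' Score scales mimic BLAST bitscores: planted orthologs draw from
#' Normal(450, 180) and decoys from Normal(200, 80), both truncated at 1.
#' These defaults give the sequence score alone a discriminability of about
#' AUC 0.90, leaving headroom for the network features to improve on it; the
#' two directional scores are the drawn score plus/minus a small
#' perturbation, so their average is the drawn score exactly.
#'
#' @param n number of nodes per network (>= 10).
#' @param edge_prob Erdos-Renyi edge probability (default 0.08, mean degree
#'   ~8 at the default `n`).
#' @param rewire_rate probability that an edge of the species-B copy is
#'   rewired to a random new position.
#' @param ortholog_fraction fraction of nodes with a planted ortholog.
#' @param decoy_rate per-node probability of one spurious homology entry.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @param degree_model `"erdos_renyi"` (default) or
#'   `"preferential_attachment"` for a heavy-tailed degree distribution
#'   closer to real interactomes.
#'
#' @return A list with elements `g1`, `g2` (igraph), `homology` (tibble
#'   `node_a`, `node_b`, `score`, `score_ab`, `score_ba`), `labels` (tibble
#'   `node_a`, `node_b` of true pairs).
#' @export
generate_network_pair <- function(n = 100, edge_prob = 0.08, rewire_rate = 0.1,
                                  ortholog_fraction = 0.5, decoy_rate = 0.1,
                                  seed = 1,
                                  degree_model = c("erdos_renyi",
                                                   "preferential_attachment")) {
  degree_model <- match.arg(degree_model)
  rates <- c(edge_prob = edge_prob, rewire_rate = rewire_rate,
             ortholog_fraction = ortholog_fraction, decoy_rate = decoy_rate)
  if (any(rates < 0 | rates > 1)) {
    abort("edge_prob, rewire_rate, ortholog_fraction and decoy_rate must lie in [0, 1].")
  }
  if (n < 10) abort("`n` must be at least 10.")
  set.seed(seed)
  names_a <- sprintf("a%04d", seq_len(n))
  names_b <- sprintf("b%04d", seq_len(n))
  g1 <- switch(degree_model,
    erdos_renyi = igraph::sample_gnp(n, edge_prob),
    preferential_attachment = igraph::sample_pa(
      n, m = max(1L, round(n * edge_prob / 2)), directed = FALSE
    )
  )
  igraph::V(g1)$name <- names_a
  g2 <- g1
  igraph::V(g2)$name <- names_b
  if (rewire_rate > 0) {
    g2 <- igraph::rewire(g2, igraph::each_edge(prob = rewire_rate,
                                               loops = FALSE, multiple = FALSE))
  }
  g1 <- igraph::set_graph_attr(g1, "species_tag", "speciesA")
  g2 <- igraph::set_graph_attr(g2, "species_tag", "speciesB")
  g1 <- igraph::set_graph_attr(g1, "weighted", FALSE)
  g2 <- igraph::set_graph_attr(g2, "weighted", FALSE)

  truncated_normal <- function(k, mean, sd) pmax(rnorm(k, mean, sd), 1)
  n_true <- round(ortholog_fraction * n)
  true_idx <- sort(sample.int(n, n_true))
  labels <- tibble::tibble(node_a = names_a[true_idx], node_b = names_b[true_idx])
  true_scores <- truncated_normal(n_true, 450, 180)

  decoy_src <- which(runif(n) < decoy_rate)
  decoy_tgt <- vapply(decoy_src, function(i) sample(setdiff(seq_len(n), i), 1L),
                      integer(1))
  decoys <- tibble::tibble(node_a = names_a[decoy_src],
                           node_b = names_b[decoy_tgt],
                           score = truncated_normal(length(decoy_src), 200, 80))

  P <- dplyr::bind_rows(
    tibble::tibble(node_a = labels$node_a, node_b = labels$node_b,
                   score = true_scores),
    decoys
  ) |>
    dplyr::group_by(.data$node_a, .data$node_b) |>
    dplyr::summarise(score = max(.data$score), .groups = "drop")
  delta <- rnorm(nrow(P), 0, 10)
  delta[P$score - abs(delta) < 1] <- 0  # keep both directional scores positive
  P$score_ab <- P$score + delta
  P$score_ba <- P$score - delta
  P <- dplyr::arrange(P, .data$node_a, .data$node_b)

  list(g1 = g1, g2 = g2, homology = P, labels = labels)
}

#' Generate paired expression matrices with shared coexpression modules
#'
#' Emulates a cross-species tissue-panel experiment: genes are grouped into
#' co-regulated modules sharing a latent tissue profile, orthologous genes
#' (same index in the two species) share the same latent profile, and every
#' measurement adds independent Normal(0, `noise_sd`) noise. With low noise
#' the coexpression networks built at cutoff 0.8 recover the module
#' structure in both species.
#'
#' @param n_genes genes per species (default 60).
#' @param n_tissues tissues/conditions (>= 5; default 13, a typical
#'   multi-organ panel).
#' @param module_count number of co-regulated modules (default 6).
#' @param noise_sd measurement noise standard deviation, on the same scale
#'   as the standard-normal latent profiles (default 0.3).
#' @param seed integer seed.
#' @return A list of two tibbles (`expr1`, `expr2`), each `gene` +
#'   one column per tissue, plus `modules` (tibble `gene1`, `gene2`,
#'   `module`).
#' @export
generate_expression_pair <- function(n_genes = 60, n_tissues = 13,
                                     module_count = 6, noise_sd = 0.3,
                                     seed = 1) {
  if (n_tissues < 5) abort("`n_tissues` must be at least 5.")
  stopifnot(n_genes >= module_count, module_count >= 1)
  set.seed(seed)
  tissues <- sprintf("tissue%02d", seq_len(n_tissues))
  profiles <- matrix(rnorm(module_count * n_tissues), module_count, n_tissues)
  module_of <- rep_len(seq_len(module_count), n_genes)
  make_expr <- function(prefix) {
    vals <- profiles[module_of, , drop = FALSE] +
      matrix(rnorm(n_genes * n_tissues, 0, noise_sd), n_genes, n_tissues)
    out <- tibble::as_tibble(as.data.frame(vals))
    names(out) <- tissues
    dplyr::bind_cols(
      tibble::tibble(gene = sprintf("%s%04d", prefix, seq_len(n_genes))),
      out
    )
  }
  expr1 <- make_expr("ga")
  expr2 <- make_expr("gb")
  list(
    expr1 = expr1, expr2 = expr2,
    modules = tibble::tibble(gene1 = expr1$gene, gene2 = expr2$gene,
                             module = module_of)
  )
}

#' Write a simulated study to the pipeline's file formats
#'
#' Emits exactly the plain-text files the command-line pipeline consumes:
#' edge lists (`network1.tsv`, `network2.tsv`), bidirectional 12-column
#' BLAST tabular files (`blast_ab.tsv`, `blast_ba.tsv`, synthetic e-values
#' of 1e-50), ortholog labels (`labels.tsv`) and, if expression data is
#' supplied, expression matrices (`expression1.tsv`, `expression2.tsv`).
#'
#' @param sim output of [generate_network_pair()].
#' @param dir output directory (created if needed).
#' @param expression optional output of [generate_expression_pair()].
#' @return Invisibly, a named character vector of the written paths.
#' @export
write_synthetic_files <- function(sim, dir, expression = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  write_edges <- function(g, file) {
    el <- igraph::as_edgelist(g)
    df <- tibble::tibble(node_a = el[, 1], node_b = el[, 2])
    # isolated nodes are encoded as self-loop lines, which load_graph() turns
    # back into edgeless retained nodes
    iso <- igraph::V(g)$name[igraph::degree(g) == 0]
    if (length(iso) > 0) {
      df <- dplyr::bind_rows(df, tibble::tibble(node_a = iso, node_b = iso))
    }
    if (!is.null(igraph::E(g)$weight)) {
      df$weight <- c(igraph::E(g)$weight, rep(1, length(iso)))
    }
    readr::write_tsv(df, file, col_names = FALSE)
    file
  }
  paths["network1"] <- write_edges(sim$g1, file.path(dir, "network1.tsv"))
  paths["network2"] <- write_edges(sim$g2, file.path(dir, "network2.tsv"))
  blast_row <- function(q, s, bits) {
    tibble::tibble(query = q, subject = s, pident = 90, length = 300,
                   mismatch = 30, gapopen = 0, qstart = 1, qend = 300,
                   sstart = 1, send = 300, evalue = 1e-50,
                   bitscore = round(bits, 2))
  }
  P <- sim$homology
  readr::write_tsv(blast_row(P$node_a, P$node_b, P$score_ab),
                   file.path(dir, "blast_ab.tsv"), col_names = FALSE)
  readr::write_tsv(blast_row(P$node_b, P$node_a, P$score_ba),
                   file.path(dir, "blast_ba.tsv"), col_names = FALSE)
  paths["blast_ab"] <- file.path(dir, "blast_ab.tsv")
  paths["blast_ba"] <- file.path(dir, "blast_ba.tsv")
  readr::write_tsv(sim$labels, file.path(dir, "labels.tsv"), col_names = FALSE)
  paths["labels"] <- file.path(dir, "labels.tsv")
  if (!is.null(expression)) {
    readr::write_tsv(expression$expr1, file.path(dir, "expression1.tsv"))
    readr::write_tsv(expression$expr2, file.path(dir, "expression2.tsv"))
    paths["expression1"] <- file.path(dir, "expression1.tsv")
    paths["expression2"] <- file.path(dir, "expression2.tsv")
  }
  invisible(paths)
}
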