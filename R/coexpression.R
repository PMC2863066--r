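#' Average probe-level expression to gene level
#'
#' Microarray platforms measure several probes per gene; downstream
#' correlation networks need one value per gene per tissue, so each gene's
#' profile is the arithmetic mean of its probes' rows. Probes without a gene
#' mapping are dropped (a count is reported).
#'
#' @param probes a data frame whose first column is the probe ID and whose
#'   remaining columns are one tissue/condition each.
#' @param probe_map a data frame with columns `probe` and `gene`, mapping each
#'   probe to exactly one gene.
#'
#' @return A tibble with first column `gene` and the same condition columns,
#'   one row per gene, genes sorted by ID.
#' @examples
#' probes <- data.frame(probe = c("p1", "p2"), t1 = c(1, 3), t2 = c(3, 5))
#' pm <- data.frame(probe = c("p1", "p2"), gene = c("g", "g"))
#' average_probes(probes, pm)  # g: (2, 4)
#' @export
average_probes <- function(probes, probe_map) {
  probes <- tibble::as_tibble(probes)
  probe_map <- tibble::as_tibble(probe_map)
  stopifnot(all(c("probe", "gene") %in% names(probe_map)))
  if (anyDuplicated(probe_map$probe)) {
    abort("Each probe must map to exactly one gene.")
  }
  names(probes)[1] <- "probe"
  unmapped <- !(probes$probe %in% probe_map$probe)
  if (any(unmapped)) {
    inform(sprintf("Dropped %d probe(s) without a gene mapping.", sum(unmapped)))
  }
  kept <- probes[!unmapped, , drop = FALSE]
  if (nrow(kept) == 0) abort("No probe overlaps the probe-to-gene map.")
  kept$gene <- probe_map$gene[match(kept$probe, probe_map$probe)]
  kept |>
    dplyr::select(-"probe") |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(dplyr::across(dplyr::everything(), mean), .groups = "drop") |>
    dplyr::arrange(.data$gene)
}

#' Spearman rank correlation
#'
#' Pearson correlation of the two vectors' rank transforms, with ties given
#' average ranks. Returns `NA` when either vector is constant (the
#' correlation is undefined).
#'
#' @param x,y numeric vectors of equal length (at least 3).
#' @return A single value in \[-1, 1\], or `NA_real_` for a constant input.
#' @examples
#' spearman_rho(c(1, 2, 3, 4), c(2, 1, 4, 3))  # 0.6
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have the same length.")
  if (length(x) < 3) abort("Need at least 3 paired observations.")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' Build a weighted coexpression network from an expression matrix
#'
#' Computes all pairwise Spearman correlations between gene expression
#' profiles across tissues and keeps an edge wherever `|rho| >= cutoff`,
#' weighted by `|rho|` (the sign is discarded after thresholding, so
#' correlated and anti-correlated gene pairs are treated identically). Genes
#' with constant expression are excluded from pairing but retained as
#' isolated nodes.
#'
#' @param expr a data frame whose first column is the gene ID and whose
#'   remaining (>= 3) columns are tissues, one averaged value per gene per
#'   tissue (see [average_probes()]); or a numeric matrix with gene rownames.
#' @param cutoff minimum `|rho|` retained, in (0, 1]; default 0.8.
#' @param species_tag label stored on the resulting graph.
#'
#' @return A weighted undirected `igraph` graph over all genes.
#' @examples
#' set.seed(1)
#' expr <- data.frame(gene = c("g1", "g2"), t(replicate(2, rnorm(6))))
#' expr[2, -1] <- expr[1, -1] * 2 + 1           # perfectly rank-correlated
#' g <- build_coexpression_network(expr, cutoff = 0.8)
#' igraph::E(g)$weight                           # 1
#' @export
build_coexpression_network <- function(expr, cutoff = 0.8, species_tag = "species") {
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 0 || cutoff > 1) {
    abort("`cutoff` must lie in (0, 1].")
  }
  if (is.data.frame(expr)) {
    genes <- as.character(expr[[1]])
    vals <- as.matrix(expr[, -1, drop = FALSE])
    mode(vals) <- "numeric"
    rownames(vals) <- genes
  } else {
    vals <- as.matrix(expr)
    genes <- rownames(vals)
    if (is.null(genes)) abort("Matrix input needs gene rownames.")
  }
  if (nrow(vals) < 2) abort("Need at least 2 genes to build a network.")
  if (ncol(vals) < 3) abort("Need at least 3 tissues/conditions for correlation.")
  if (anyDuplicated(genes)) abort("Duplicate gene IDs; average probes first.")

  constant <- apply(vals, 1, function(r) length(unique(r)) == 1)
  rho <- matrix(NA_real_, nrow(vals), nrow(vals), dimnames = list(genes, genes))
  if (sum(!constant) >= 2) {
    rho[!constant, !constant] <- stats::cor(t(vals[!constant, , drop = FALSE]),
                                            method = "spearman")
  }
  keep <- which(upper.tri(rho) & !is.na(rho) & abs(rho) >= cutoff, arr.ind = TRUE)
  el <- tibble::tibble(
    node_a = genes[keep[, 1]],
    node_b = genes[keep[, 2]],
    weight = abs(rho[keep])
  )
  g <- igraph::graph_from_data_frame(
    el, directed = FALSE,
    vertices = data.frame(name = sort(genes), stringsAsFactors = FALSE)
  )
  g <- igraph::set_graph_attr(g, "species_tag", species_tag)
  igraph::set_graph_attr(g, "weighted", TRUE)
}

#' Read an expression matrix TSV
#'
#' First column gene (or probe) ID, remaining columns one per tissue, header
#' row with tissue names.
#'
#' @param path TSV file path.
#' @return A tibble (first column character ID, rest numeric).
#' @export
read_expression <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
}
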