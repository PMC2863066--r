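#' Reference benchmark AUC grids
#'
#' Bundled cross-validated AUC grids (percent) for the classical benchmark
#' species pairs (fly, yeast, mouse, human protein-interaction networks and
#' the mouse-human coexpression network): one grid for classifiers trained
#' on the sequence score alone, one for classifiers trained on all nine
#' features. They serve as fixed inputs for the average-rank machinery —
#' e.g. on the protein-interaction rows of the sequence-only grid the
#' logistic column has average rank 1.17, and on the all-features grid
#' AdaBoost has 1.67.
#'
#' @param feature_set `"blast"` (sequence-score-only classifiers) or
#'   `"network"` (all nine features).
#' @return A tibble with columns `dataset`, `network` (`"ppi"` or
#'   `"coexpression"`) and one AUC column per classifier.
#' @examples
#' g <- published_auc_grid("blast")
#' average_rank(dplyr::filter(g, network == "ppi")[, -2])
#' @export
published_auc_grid <- function(feature_set = c("blast", "network")) {
  feature_set <- match.arg(feature_set)
  f <- system.file(
    "extdata",
    if (feature_set == "blast") "blast_only_auc_grid.tsv" else
      "network_features_auc_grid.tsv",
    package = "orthonet", mustWork = TRUE
  )
  readr::read_tsv(f, col_types = readr::cols(
    dataset = readr::col_character(), network = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
}
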