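#' Parse BLAST tabular output into a directional score table
#'
#' Consumes 12-column tabular BLAST output (`-outfmt 6`: query, subject,
#' pident, length, mismatch, gapopen, qstart, qend, sstart, send, evalue,
#' bitscore). Hits with an e-value above the cutoff are discarded; when the
#' same query/subject pair occurs more than once (multiple HSPs), the
#' maximum bitscore is kept.
#'
#' @param source file path, or a data frame already holding the 12 columns.
#' @param evalue_cutoff maximum e-value retained; default `1e-10`.
#' @return A tibble with columns `query`, `subject`, `bitscore`.
#' @examples
#' hits <- data.frame(query = "a", subject = "x", pident = 99, length = 100,
#'                    mismatch = 1, gapopen = 0, qstart = 1, qend = 100,
#'                    sstart = 1, send = 100, evalue = 1e-20, bitscore = 481)
#' parse_blast_tabular(hits)
#' @export
parse_blast_tabular <- function(source, evalue_cutoff = 1e-10) {
  blast_cols <- c("query", "subject", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send",
                  "evalue", "bitscore")
  if (is.character(source) && length(source) == 1) {
    tab <- readr::read_tsv(
      source, col_names = blast_cols, comment = "#",
      col_types = readr::cols(
        query = readr::col_character(), subject = readr::col_character(),
        .default = readr::col_double()
      ),
      progress = FALSE
    )
    probs <- readr::problems(tab)
    n_bad <- sum(is.na(tab$evalue) | is.na(tab$bitscore))
    if (nrow(probs) > 0 || n_bad > 0) {
      line <- if (nrow(probs) > 0) probs$row[1] else
        which(is.na(tab$evalue) | is.na(tab$bitscore))[1]
      abort(sprintf("Malformed BLAST tabular line %d in '%s' (12 columns expected).",
                    line, source))
    }
  } else {
    tab <- tibble::as_tibble(source)
    if (ncol(tab) != 12) {
      abort(sprintf("BLAST tabular input has %d columns; 12 expected.", ncol(tab)))
    }
    names(tab) <- blast_cols
  }
  tab |>
    dplyr::filter(.data$evalue <= evalue_cutoff) |>
    dplyr::group_by(.data$query, .data$subject) |>
    dplyr::summarise(bitscore = max(.data$bitscore), .groups = "drop") |>
    dplyr::arrange(.data$query, .data$subject)
}

#' Average bidirectional BLAST scores into a homology map
#'
#' Builds the sparse cross-species mapping from the two directional BLAST
#' runs (A vs B and B vs A): each candidate pair's score is the mean of its
#' two directional bitscores. Pairs hit in only one direction keep that
#' single score (a count is reported). The result is both the BLAST feature
#' and the homology weight used inside the graph kernels.
#'
#' @param ab directional table from [parse_blast_tabular()] with species-A
#'   queries and species-B subjects.
#' @param ba the reverse-direction table (species-B queries).
#' @return A tibble with columns `node_a`, `node_b` (always species A and B
#'   respectively), `score` (averaged bitscore), `score_ab`, `score_ba`
#'   (directional bitscores, `NA` when missing), sorted by pair.
#' @examples
#' ab <- tibble::tibble(query = "a", subject = "x", bitscore = 300)
#' ba <- tibble::tibble(query = "x", subject = "a", bitscore = 500)
#' average_bidirectional(ab, ba)$score  # 400
#' @export
average_bidirectional <- function(ab, ba) {
  fwd <- tibble::as_tibble(ab)
  rev <- tibble::as_tibble(ba)
  fwd <- tibble::tibble(node_a = as.character(fwd$query),
                        node_b = as.character(fwd$subject),
                        score_ab = fwd$bitscore)
  rev <- tibble::tibble(node_a = as.character(rev$subject),
                        node_b = as.character(rev$query),
                        score_ba = rev$bitscore)
  P <- dplyr::full_join(fwd, rev, by = c("node_a", "node_b"))
  one_sided <- sum(is.na(P$score_ab) | is.na(P$score_ba))
  if (one_sided > 0) {
    inform(sprintf("%d pair(s) hit in one direction only; using the single score.",
                   one_sided))
  }
  P |>
    dplyr::mutate(
      score = dplyr::coalesce((.data$score_ab + .data$score_ba) / 2,
                              .data$score_ab, .data$score_ba)
    ) |>
    dplyr::select("node_a", "node_b", "score", "score_ab", "score_ba") |>
    dplyr::arrange(.data$node_a, .data$node_b)
}

#' Reciprocal-best-hit ortholog prediction
#'
#' The classical sequence-only baseline: a pair (a, b) is predicted
#' orthologous when b is a's highest-scoring match in species B *and* a is
#' b's highest-scoring match in species A, using the averaged bidirectional
#' scores. Ties for best hit are broken by lexicographic node ID, and pairs
#' involved in a tie are flagged.
#'
#' @param homology a homology map from [average_bidirectional()] (columns
#'   `node_a`, `node_b`, `score`).
#' @return A tibble with columns `node_a`, `node_b`, `score`, `tie`
#'   (logical), one row per predicted pair; a partial matching, so each node
#'   appears at most once.
#' @examples
#' P <- tibble::tibble(node_a = c("a", "a", "b"), node_b = c("x", "y", "y"),
#'                     score = c(500, 100, 300))
#' rbh_predict(P)  # (a,x) and (b,y)
#' @export
rbh_predict <- function(homology) {
  P <- tibble::as_tibble(homology)
  stopifnot(all(c("node_a", "node_b", "score") %in% names(P)))
  if (nrow(P) == 0) {
    return(tibble::tibble(node_a = character(), node_b = character(),
                          score = numeric(), tie = logical()))
  }
  best_of <- function(df, key) {
    df |>
      dplyr::group_by(dplyr::across(dplyr::all_of(key))) |>
      dplyr::arrange(dplyr::desc(.data$score), .data$node_a, .data$node_b,
                     .by_group = TRUE) |>
      dplyr::summarise(
        best_a = .data$node_a[1], best_b = .data$node_b[1],
        tie = sum(.data$score == max(.data$score)) > 1,
        .groups = "drop"
      )
  }
  best_fwd <- best_of(P, "node_a")   # for each a: best b
  best_rev <- best_of(P, "node_b")   # for each b: best a
  P |>
    dplyr::inner_join(dplyr::select(best_fwd, "node_a", pred_b = "best_b",
                                    tie_a = "tie"), by = "node_a") |>
    dplyr::inner_join(dplyr::select(best_rev, "node_b", pred_a = "best_a",
                                    tie_b = "tie"), by = "node_b") |>
    dplyr::filter(.data$node_b == .data$pred_b, .data$node_a == .data$pred_a) |>
    dplyr::transmute(.data$node_a, .data$node_b, .data$score,
                     tie = .data$tie_a | .data$tie_b) |>
    dplyr::arrange(.data$node_a, .data$node_b)
}
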