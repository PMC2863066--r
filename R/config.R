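#' Pipeline configuration
#'
#' Collects every tunable parameter of the ortholog-detection pipeline in one
#' list, pre-filled with the defaults used throughout: BLAST e-value cutoff
#' 1e-10, absolute Spearman correlation cutoff 0.8 for coexpression edges,
#' random-walk damping lambda = 0.01, neighborhood hop radii k = 1 and 2, and
#' 10-fold cross-validation.
#'
#' @param ... named overrides for any default (unknown names are rejected).
#' @param file optional path to a YAML file whose top-level keys override the
#'   defaults before `...` is applied.
#'
#' @return A named list with class `"ortho_config"`.
#'
#' @details Parameters and units:
#' \describe{
#'   \item{evalue_cutoff}{BLAST e-value threshold; hits above it are dropped.}
#'   \item{cor_cutoff}{minimum `|rho|` for a coexpression edge, in (0, 1].}
#'   \item{lambda}{random-walk damping; must keep `lambda * rho(K) < 1`.}
#'   \item{k_hops}{hop radii for neighborhood kernels (topological hops).}
#'   \item{folds}{cross-validation fold count.}
#'   \item{sp_epsilon_unit, sp_epsilon_weighted}{shortest-path length-agreement
#'     tolerance for unweighted (hop-count) and correlation-weighted
#'     distances respectively.}
#'   \item{rw_weight_gate}{`NULL` for the soft product form of edge-weight
#'     matching in the random-walk kernel, or a tolerance `tau` to require
#'     `|w_C - w_Z| <= tau` instead.}
#'   \item{hits_tol, hits_max_iter}{HITS power-iteration stopping rule.}
#' }
#'
#' @examples
#' cfg <- ortho_config(lambda = 0.005)
#' cfg$lambda
#' @export
ortho_config <- function(..., file = NULL) {
  cfg <- list(
    evalue_cutoff      = 1e-10,
    cor_cutoff         = 0.8,
    lambda             = 0.01,
    k_hops             = c(1L, 2L),
    folds              = 10L,
    sp_epsilon_unit    = 0,
    sp_epsilon_weighted = 0.05,
    rw_weight_gate     = NULL,
    hits_tol           = 1e-8,
    hits_max_iter      = 1000L
  )
  apply_over <- function(cfg, over, where) {
    if (length(over) == 0) return(cfg)
    bad <- setdiff(names(over), names(cfg))
    if (length(bad) > 0 || is.null(names(over)) || any(names(over) == "")) {
      abort(paste0("Unknown configuration option(s) ", where, ": ",
                   paste(bad, collapse = ", ")))
    }
    cfg[names(over)] <- over
    cfg
  }
  if (!is.null(file)) {
    cfg <- apply_over(cfg, yaml::read_yaml(file), paste0("in '", file, "'"))
  }
  cfg <- apply_over(cfg, list(...), "in call")
  structure(cfg, class = "ortho_config")
}

#' @export
print.ortho_config <- function(x, ...) {
  cat("<ortho_config>\n")
  for (nm in names(x)) {
    val <- x[[nm]]
    cat(sprintf("  %-20s %s\n", nm,
                if (is.null(val)) "NULL" else paste(format(val), collapse = ", ")))
  }
  invisible(x)
}
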