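ORTHO_ALGORITHMS <- c("boosted_tree", "naive_bayes", "svm", "logistic", "ensemble")

.check_labels <- function(label) {
  if (!is.factor(label)) label <- factor(label, levels = c("non-ortholog", "ortholog"))
  tab <- table(label)
  if (length(tab) < 2 || any(tab == 0)) {
    abort("Training data must contain at least one ortholog and one non-ortholog.")
  }
  label
}

.standardize <- function(X, center = NULL, scale = NULL) {
  if (is.null(center)) {
    center <- colMeans(X)
    scale <- apply(X, 2, stats::sd)
    scale[scale == 0 | !is.finite(scale)] <- 1
  }
  Xs <- sweep(sweep(X, 2, center, "-"), 2, scale, "/")
  list(X = Xs, center = center, scale = scale)
}

.fit_one <- function(algorithm, Xs, y, seed) {
  set.seed(seed)
  switch(
    algorithm,
    boosted_tree = xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = 3, eta = 0.3,
                    nthread = 1, seed = seed),
      data = xgboost::xgb.DMatrix(Xs, label = as.numeric(y == "ortholog"),
                                  nthread = 1),
      nrounds = 40, verbose = 0
    ),
    naive_bayes = {
      fit <- e1071::naiveBayes(x = as.data.frame(Xs), y = y)
      # guard against zero within-class variance (constant feature in a class)
      fit$tables <- lapply(fit$tables, function(tb) {
        tb[, 2] <- pmax(tb[, 2], 1e-6)
        tb
      })
      fit
    },
    svm = {
      fit <- e1071::svm(x = Xs, y = y, kernel = "radial", scale = FALSE)
      dv <- .svm_decision(fit, Xs)
      # Platt scaling of the decision values (deterministic calibration)
      calib <- suppressWarnings(
        glm(pos ~ dv, family = binomial(),
            data = data.frame(pos = y == "ortholog", dv = dv))
      )
      cf <- coef(calib)
      cf[is.na(cf)] <- 0
      list(svm = fit, calib = cf)
    },
    logistic = suppressWarnings(
      glm(y ~ ., family = binomial(),
          data = data.frame(y = y == "ortholog", as.data.frame(Xs)))
    ),
    abort(sprintf("Unknown algorithm '%s'.", algorithm))
  )
}

# signed SVM decision value, oriented so larger = more ortholog-like
.svm_decision <- function(fit, Xs) {
  pr <- predict(fit, Xs, decision.values = TRUE)
  dv_mat <- attr(pr, "decision.values")
  dv <- as.numeric(dv_mat)
  # libsvm's sign convention: positive decision value favors the class named
  # first in the column label
  if (startsWith(colnames(dv_mat)[1], "ortholog")) dv else -dv
}

#' Train an ortholog classifier
#'
#' Fits one of the supported classifiers on a labeled feature table:
#' AdaBoost-style boosted trees (`boosted_tree`, via gradient-boosted
#' stumps/trees), Gaussian naive Bayes, an RBF support vector machine with
#' Platt-scaled probabilities, logistic regression, or their `ensemble`
#' (unweighted mean of the four members' predicted probabilities). Features
#' are z-scored inside the model using the statistics of the training data
#' only, so cross-validation never leaks fold information.
#'
#' @param table a feature table from [feature_table()] (or any data frame
#'   with the requested feature columns and a `label` column with levels
#'   `non-ortholog` / `ortholog`).
#' @param algorithm one of `"boosted_tree"`, `"naive_bayes"`, `"svm"`,
#'   `"logistic"`, `"ensemble"`.
#' @param seed integer seed making the fit deterministic.
#' @param features which feature columns to use; defaults to all of
#'   [ortho_features()] present in `table` (`"blast"` alone reproduces the
#'   sequence-only classifier).
#' @return An object of class `ortho_model`; [predict()] on it returns the
#'   probability that each row is an ortholog.
#' @export
train_classifier <- function(table, algorithm = ORTHO_ALGORITHMS, seed = 1,
                             features = NULL) {
  algorithm <- match.arg(algorithm)
  table <- tibble::as_tibble(table)
  if (is.null(features)) features <- intersect(ortho_features(), names(table))
  stopifnot(length(features) > 0, all(features %in% names(table)))
  y <- .check_labels(table$label)
  X <- as.matrix(table[, features, drop = FALSE])
  std <- .standardize(X)
  fits <- if (algorithm == "ensemble") {
    members <- setdiff(ORTHO_ALGORITHMS, "ensemble")
    setNames(lapply(members, .fit_one, Xs = std$X, y = y, seed = seed), members)
  } else {
    .fit_one(algorithm, std$X, y, seed)
  }
  structure(
    list(algorithm = algorithm, seed = seed, features = features,
         center = std$center, scale = std$scale, fit = fits,
         calibration = if (algorithm %in% c("svm", "ensemble"))
           "Platt scaling of SVM decision values" else NULL,
         n_train = nrow(table)),
    class = "ortho_model"
  )
}

.predict_one <- function(algorithm, fit, Xs) {
  switch(
    algorithm,
    boosted_tree = as.numeric(predict(fit, xgboost::xgb.DMatrix(Xs, nthread = 1))),
    naive_bayes = as.numeric(
      predict(fit, as.data.frame(Xs), type = "raw")[, "ortholog"]
    ),
    svm = {
      dv <- .svm_decision(fit$svm, Xs)
      as.numeric(stats::plogis(fit$calib[1] + fit$calib[2] * dv))
    },
    logistic = {
      cf <- coef(fit)
      cf[is.na(cf)] <- 0
      as.numeric(stats::plogis(cbind(1, Xs) %*% cf))
    }
  )
}

#' @describeIn train_classifier Predicted ortholog probabilities for new
#'   pairs (numeric vector in \[0, 1\]).
#' @param object an `ortho_model`.
#' @param newdata data frame containing the model's feature columns.
#' @param ... unused.
#' @export
predict.ortho_model <- function(object, newdata, ...) {
  X <- as.matrix(tibble::as_tibble(newdata)[, object$features, drop = FALSE])
  Xs <- .standardize(X, object$center, object$scale)$X
  if (object$algorithm == "ensemble") {
    probs <- vapply(names(object$fit),
                    function(a) .predict_one(a, object$fit[[a]], Xs),
                    numeric(nrow(Xs)))
    rowMeans(matrix(probs, nrow = nrow(Xs)))
  } else {
    .predict_one(object$algorithm, object$fit, Xs)
  }
}

#' @export
print.ortho_model <- function(x, ...) {
  cat(sprintf("<ortho_model: %s | %d features | n = %d | seed = %d>\n",
              x$algorithm, length(x$features), x$n_train, x$seed))
  invisible(x)
}

#' @method tidy ortho_model
#' @export
tidy.ortho_model <- function(x, ...) {
  out <- tibble::tibble(feature = x$features,
                        center = unname(x$center), scale = unname(x$scale))
  if (x$algorithm == "logistic") {
    cf <- coef(x$fit)
    out$coefficient <- unname(cf[match(make.names(x$features), names(cf))])
  }
  out
}

#' @method glance ortho_model
#' @export
glance.ortho_model <- function(x, ...) {
  tibble::tibble(algorithm = x$algorithm, n_features = length(x$features),
                 n_train = x$n_train, seed = x$seed,
                 calibration = x$calibration %||% NA_character_)
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a randomly chosen positive
#' outscores a randomly chosen negative, counting ties as one half, reported
#' in percent (0-100). Invariant under any strictly monotone transform of
#' the scores.
#'
#' @param scores numeric prediction scores (higher = more ortholog-like).
#' @param labels parallel labels; a factor with level `"ortholog"` positive,
#'   or a logical/0-1 vector.
#' @return AUC in percent.
#' @examples
#' auc_score(c(3, 1, 2), c(TRUE, FALSE, TRUE))  # 100
#' @export
auc_score <- function(scores, labels) {
  pos <- if (is.factor(labels) || is.character(labels)) {
    labels == "ortholog"
  } else {
    as.logical(labels)
  }
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    abort("AUC is undefined: both classes must be present.")
  }
  r <- rank(scores, ties.method = "average")
  100 * (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Cross-validated AUC of an ortholog classifier
#'
#' Stratified k-fold cross-validation: within each class, rows are shuffled
#' (deterministically, from `seed`) and dealt round-robin into folds, so
#' fold class ratios match the table's within one instance. Out-of-fold
#' predicted probabilities are pooled into a single AUC.
#'
#' @inheritParams train_classifier
#' @param folds number of folds (default 10).
#' @return AUC in percent.
#' @export
cross_validate <- function(table, algorithm = ORTHO_ALGORITHMS, folds = 10,
                           seed = 1, features = NULL) {
  algorithm <- match.arg(algorithm)
  table <- tibble::as_tibble(table)
  if (!is.numeric(folds) || folds < 2) abort("`folds` must be at least 2.")
  y <- .check_labels(table$label)
  if (any(table(y) < 2)) {
    abort(paste("A class has a single instance, so some training fold would",
                "be single-class; use fewer folds or more data."))
  }
  set.seed(seed)
  fold_id <- integer(nrow(table))
  for (cls in levels(y)) {
    idx <- sample(which(y == cls))
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  prob <- rep(NA_real_, nrow(table))
  for (f in sort(unique(fold_id))) {
    train <- table[fold_id != f, , drop = FALSE]
    test <- table[fold_id == f, , drop = FALSE]
    model <- train_classifier(train, algorithm, seed = seed, features = features)
    prob[fold_id == f] <- predict(model, test)
  }
  auc_score(prob, y)
}

#' Average rank of methods across datasets
#'
#' Within each dataset the methods are ranked by decreasing AUC (ties get
#' the average of the tied ranks); ranks are then averaged over datasets.
#' The method with the smallest average rank performs best overall.
#'
#' @param grid a data frame with one row per dataset: an optional first
#'   `dataset` column (character) and one numeric AUC column per method.
#' @return A tibble with columns `method` and `avg_rank`, in the grid's
#'   column order.
#' @examples
#' g <- tibble::tibble(m1 = c(90, 80), m2 = c(85, 85))
#' average_rank(g)
#' @export
average_rank <- function(grid) {
  grid <- tibble::as_tibble(grid)
  num <- vapply(grid, is.numeric, logical(1))
  aucs <- as.matrix(grid[, num, drop = FALSE])
  if (ncol(aucs) < 2) abort("Need at least two method columns to rank.")
  ranks <- t(apply(aucs, 1, function(r) rank(-r, ties.method = "average")))
  tibble::tibble(method = colnames(aucs), avg_rank = unname(colMeans(ranks)))
}

#' Cross-validated comparison of detection methods over several datasets
#'
#' Runs [cross_validate()] for each requested classifier on each labeled
#' feature table and summarizes the results as an AUC grid (datasets x
#' methods, in percent) with per-method average ranks — the layout used to
#' compare ortholog-detection methods across species pairs.
#'
#' @param tables a named list of feature tables (one per dataset /
#'   species pair).
#' @param algorithms classifiers to compare.
#' @param folds,seed,features passed to [cross_validate()].
#' @return An object of class `ortho_eval`: list with `auc` (wide tibble,
#'   `dataset` + one column per method) and `avg_rank` (from
#'   [average_rank()]).
#' @export
evaluate_methods <- function(tables, algorithms = ORTHO_ALGORITHMS,
                             folds = 10, seed = 1, features = NULL) {
  stopifnot(is.list(tables), length(tables) > 0)
  if (is.null(names(tables)) || any(names(tables) == "")) {
    names(tables) <- paste0("dataset", seq_along(tables))
  }
  grid <- purrr::map_dfr(names(tables), function(ds) {
    row <- purrr::map_dbl(algorithms, function(algo) {
      cross_validate(tables[[ds]], algo, folds = folds, seed = seed,
                     features = features)
    })
    tibble::tibble(dataset = ds, !!!setNames(as.list(row), algorithms))
  })
  structure(
    list(auc = grid, avg_rank = average_rank(grid),
         folds = folds, seed = seed),
    class = "ortho_eval"
  )
}

#' @export
print.ortho_eval <- function(x, ...) {
  cat(sprintf("<ortho_eval: %d dataset(s), %d-fold CV, AUC in percent>\n",
              nrow(x$auc), x$folds))
  print(x$auc)
  cat("Average ranks:\n")
  print(x$avg_rank)
  invisible(x)
}

#' @method tidy ortho_eval
#' @export
tidy.ortho_eval <- function(x, ...) {
  x$auc |>
    tidyr::pivot_longer(-"dataset", names_to = "method", values_to = "auc") |>
    dplyr::left_join(dplyr::rename(x$avg_rank, method_avg_rank = "avg_rank"),
                     by = "method")
}

#' @method glance ortho_eval
#' @export
glance.ortho_eval <- function(x, ...) {
  best <- x$avg_rank[which.min(x$avg_rank$avg_rank), ]
  tibble::tibble(n_datasets = nrow(x$auc),
                 n_methods = nrow(x$avg_rank),
                 folds = x$folds, seed = x$seed,
                 best_method = best$method, best_avg_rank = best$avg_rank)
}

#' @method autoplot ortho_eval
#' @export
autoplot.ortho_eval <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$method, y = .data$auc,
                                 group = .data$dataset, color = .data$dataset)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = NULL, y = "Cross-validated AUC (%)",
                  title = "Ortholog detection performance by method") +
    ggplot2::theme_minimal()
}

#' Feature separation plot
#'
#' Boxplots of each feature by label — a quick look at how well individual
#' features separate planted or curated orthologs from the remaining
#' BLAST-matched pairs.
#'
#' @param table a labeled feature table from [feature_table()].
#' @return A ggplot object.
#' @export
plot_feature_separation <- function(table) {
  tibble::as_tibble(table) |>
    tidyr::pivot_longer(dplyr::any_of(ortho_features()),
                        names_to = "feature", values_to = "value") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$label, y = .data$value,
                                 fill = .data$label)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
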