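separable_table <- function(n_pos = 15, n_neg = 15) {
  tibble::tibble(
    blast = c(rnorm(n_pos, 900, 5), rnorm(n_neg, 10, 5)),
    degree = runif(n_pos + n_neg),
    label = factor(rep(c("ortholog", "non-ortholog"), c(n_pos, n_neg)),
                   levels = c("non-ortholog", "ortholog"))
  )
}

test_that("every classifier separates a linearly separable toy table at training time", {
  set.seed(1)
  tab <- separable_table()
  for (algo in c("boosted_tree", "naive_bayes", "svm", "logistic", "ensemble")) {
    model <- train_classifier(tab, algo, seed = 1)
    expect_equal(auc_score(predict(model, tab), tab$label), 100,
                 info = algo)
  }
  expect_error(train_classifier(dplyr::filter(tab, label == "ortholog"), "logistic"),
               "at least one")
})

test_that("the ensemble probability is the unweighted mean of its four members", {
  set.seed(2)
  tab <- separable_table()
  ens <- train_classifier(tab, "ensemble", seed = 3)
  members <- lapply(c("boosted_tree", "naive_bayes", "svm", "logistic"),
                    function(a) train_classifier(tab, a, seed = 3))
  member_probs <- sapply(members, function(m) predict(m, tab))
  expect_equal(predict(ens, tab), rowMeans(member_probs), tolerance = 1e-12)
})

test_that("AUC matches exhaustive pair counting, including ties, and handles degenerate labels", {
  expect_equal(auc_score(c(3, 1, 2), c(TRUE, FALSE, TRUE)), 100)
  expect_equal(auc_score(1:4, c(TRUE, TRUE, FALSE, FALSE)), 0)
  set.seed(121)
  for (rep in 1:60) {
    n <- sample(4:50, 1)
    scores <- sample(1:8, n, replace = TRUE)  # heavy ties
    pos <- runif(n) < 0.5
    if (!any(pos) || all(pos)) next
    expect_equal(auc_score(scores, pos), auc_brute(scores, pos))
  }
  expect_error(auc_score(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("AUC agrees with an independent ROC library", {
  set.seed(141)
  for (rep in 1:10) {
    n <- sample(20:120, 1)
    scores <- rnorm(n)
    pos <- runif(n) < 0.4
    if (!any(pos) || all(pos)) next
    ref <- as.numeric(pROC::auc(pROC::roc(response = pos, predictor = scores,
                                          quiet = TRUE, direction = "<")))
    expect_equal(auc_score(scores, pos), 100 * ref, tolerance = 1e-10)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(131)
  scores <- rnorm(80)
  pos <- runif(80) < 0.4
  base <- auc_score(scores, pos)
  expect_equal(auc_score(exp(scores), pos), base)
  expect_equal(auc_score(rank(scores), pos), base)
})

test_that("cross-validation is stratified, deterministic, and near-chance on shuffled labels", {
  set.seed(3)
  tab <- separable_table(40, 40)
  a1 <- cross_validate(tab, "logistic", folds = 10, seed = 7)
  a2 <- cross_validate(tab, "logistic", folds = 10, seed = 7)
  expect_identical(a1, a2)
  expect_equal(a1, 100)

  # null labels: pooled CV AUC stays near 50
  set.seed(4)
  null_tab <- tibble::tibble(
    blast = rnorm(500), degree = rnorm(500),
    label = factor(sample(rep(c("ortholog", "non-ortholog"), 250)),
                   levels = c("non-ortholog", "ortholog"))
  )
  null_auc <- cross_validate(null_tab, "logistic", folds = 10, seed = 5)
  expect_gt(null_auc, 43)
  expect_lt(null_auc, 57)

  expect_error(
    cross_validate(tibble::tibble(blast = rnorm(6),
                                  label = factor(c("ortholog", rep("non-ortholog", 5)),
                                                 levels = c("non-ortholog", "ortholog"))),
                   "logistic", folds = 3),
    "single instance"
  )
})

test_that("average ranks follow descending AUC with averaged ties", {
  always_best <- tibble::tibble(dataset = paste0("d", 1:7),
                                m1 = 90 + 1:7, m2 = 80 + 1:7, m3 = 70 + 1:7,
                                m4 = 60 + 1:7, m5 = 50 + 1:7)
  r <- average_rank(always_best)
  expect_equal(r$avg_rank[r$method == "m1"], 1)

  tied <- tibble::tibble(m1 = c(90, 85), m2 = c(90, 85))
  expect_equal(average_rank(tied)$avg_rank, c(1.5, 1.5))
})

test_that("evaluate_methods produces a tidy report with ranks, and broom methods work", {
  set.seed(6)
  tabs <- list(ds1 = separable_table(12, 12), ds2 = separable_table(12, 12))
  ev <- evaluate_methods(tabs, algorithms = c("logistic", "naive_bayes"),
                         folds = 4, seed = 2)
  expect_s3_class(ev, "ortho_eval")
  expect_equal(dim(ev$auc), c(2, 3))
  td <- tidy(ev)
  expect_identical(names(td), c("dataset", "method", "auc", "method_avg_rank"))
  expect_equal(nrow(td), 4)
  gl <- glance(ev)
  expect_equal(gl$n_datasets, 2)
  expect_s3_class(autoplot(ev), "ggplot")

  model <- train_classifier(tabs$ds1, "logistic", seed = 1)
  expect_identical(tidy(model)$feature, c("blast", "degree"))
  expect_equal(glance(model)$algorithm, "logistic")
})
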