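# exhaustive-threshold ROC and pairwise-ranking AUC, used as oracles
brute_roc_points <- function(scores, actual) {
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n_pos <- sum(actual == "lie")
  n_neg <- sum(actual == "truth")
  t(vapply(thr, function(th) {
    c(fpr = sum(scores >= th & actual == "truth") / n_neg,
      tpr = sum(scores >= th & actual == "lie") / n_pos)
  }, numeric(2)))
}

pairwise_auc <- function(scores, actual) {
  pos <- scores[actual == "lie"]
  neg <- scores[actual == "truth"]
  grid <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(grid)
}

test_that("confusion matrix counts and accuracy follow the definitions", {
  cm <- confusion_matrix(c("lie", "lie", "truth", "truth"),
                         c("lie", "truth", "truth", "lie"))
  expect_equal(cm[c("tp", "fn", "tn", "fp")], list(tp = 1, fn = 1, tn = 1, fp = 1))
  expect_equal(cm$accuracy, 50)

  perfect <- confusion_matrix(rep(c("lie", "truth"), 5), rep(c("lie", "truth"), 5))
  expect_equal(perfect$fp + perfect$fn, 0)
  expect_equal(perfect$accuracy, 100)

  expect_error(confusion_matrix(c("lie"), c("lie", "truth")), "length")
  expect_error(confusion_matrix(c("lie", "maybe"), c("lie", "lie")), "unknown label")
})

test_that("TPR and FPR come from the count ratios", {
  cm <- structure(list(tp = 3, fp = 2, tn = 4, fn = 1, n = 10, accuracy = 70),
                  class = "confusion_matrix")
  expect_equal(tpr_fpr(cm), c(tpr = 0.75, fpr = 1 / 3))

  all_pos <- confusion_matrix(c("lie", "truth", "truth"), rep("lie", 3))
  expect_equal(tpr_fpr(all_pos), c(tpr = 1, fpr = 1))

  one_class <- structure(list(tp = 2, fp = 0, tn = 0, fn = 1, n = 3,
                              accuracy = 2 / 3 * 100),
                         class = "confusion_matrix")
  expect_error(tpr_fpr(one_class), "undefined")
})

test_that("ROC anchors, monotonicity and degenerate score handling", {
  # perfect ranking passes through (0, 1)
  r <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c("lie", "lie", "truth", "truth"))
  expect_true(any(r$points$fpr == 0 & r$points$tpr == 1))
  expect_equal(auc(r), 1)

  # constant scores collapse to the chance diagonal
  r2 <- roc_curve(rep(0.5, 6), rep(c("lie", "truth"), 3))
  expect_equal(nrow(r2$points), 2)
  expect_equal(auc(r2), 0.5)

  expect_error(roc_curve(c(1, 2), c("lie", "lie")), "both classes")

  set.seed(9)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    scores <- round(runif(n), 2)  # rounding forces ties
    actual <- ifelse(runif(n) < 0.4, "lie", "truth")
    if (length(unique(actual)) < 2) next
    r3 <- roc_curve(scores, actual)
    expect_true(all(diff(r3$points$fpr) >= 0))
    expect_true(all(diff(r3$points$tpr) >= 0))
    expect_equal(r3$points$fpr[1], 0)
    expect_equal(r3$points$tpr[nrow(r3$points)], 1)
    expect_equal(as.matrix(r3$points[, c("fpr", "tpr")]),
                 brute_roc_points(scores, actual),
                 ignore_attr = TRUE)
  }
})

test_that("trapezoidal AUC equals the pairwise-ranking statistic", {
  # worked example: 3 of the 4 (lie, truth) pairs correctly ranked
  scores <- c(0.9, 0.8, 0.7, 0.6)
  actual <- c("lie", "truth", "lie", "truth")
  expect_equal(auc(roc_curve(scores, actual)), 0.75)
  expect_equal(pairwise_auc(scores, actual), 0.75)

  set.seed(10)
  for (i in 1:100) {
    n <- sample(4:50, 1)
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)
    actual <- c("lie", "truth",
                ifelse(runif(n - 2) < 0.5, "lie", "truth"))
    expect_equal(auc(roc_curve(scores, actual)),
                 pairwise_auc(scores, actual),
                 tolerance = 1e-12)
  }
})

test_that("stratified splits are exact, disjoint and label-balanced", {
  tab <- extract_features(simulate_experiment(sim_config(seed = 1)))
  parts <- split_train_val_test(tab, c(0.6, 0.2, 0.2), seed = 5)
  expect_equal(vapply(parts, nrow, integer(1)),
               c(train = 120L, val = 40L, test = 40L))

  key <- function(d) paste(d$subject, d$session)
  all_keys <- sort(unname(unlist(lapply(parts, key))))
  expect_equal(all_keys, sort(key(tab)))
  expect_equal(sum(duplicated(all_keys)), 0)

  global <- mean(tab$label == "lie")
  for (p in parts) {
    expect_lte(abs(sum(p$label == "lie") - global * nrow(p)), 1)
  }
  expect_identical(split_train_val_test(tab, seed = 5),
                   parts)
  expect_error(split_train_val_test(tab, c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("LOSO folds cover each subject exactly once and score well at default effect", {
  tab <- extract_features(simulate_experiment(sim_config(seed = 14)))
  res <- loso_evaluate(tab, "m3", train_config(seed = 14))
  expect_equal(res$per_subject$subject, 1:10)
  expect_equal(res$per_subject$n, rep(20, 10))
  expect_equal(res$mean_accuracy, mean(res$per_subject$accuracy))
  expect_gte(res$mean_accuracy, 75)
  expect_error(loso_evaluate(tab[tab$subject == 1, ], "knn"), ">= 2 subjects")
})

test_that("null-effect LOSO accuracy stays at chance level", {
  tab <- extract_features(simulate_experiment(null_config(seed = 23)))
  half <- 100 * 1.96 * sqrt(0.25 / nrow(tab))
  for (k in c("m3", "knn", "svm_linear")) {
    res <- loso_evaluate(tab, k, train_config(seed = 23))
    expect_lt(abs(res$mean_accuracy - 50), half + 5)
  }
})

test_that("subject sample test emits a reproducible 30-row grid matching confusion counts", {
  tab <- extract_features(simulate_experiment(sim_config(seed = 6)))
  cfg <- train_config(seed = 6)
  models <- list(
    nn_m3 = train_classifier("m3", tab, cfg),
    knn = train_classifier("knn", tab, cfg)
  )
  grid <- subject_sample_test(tab, models, n_per_subject = 3, seed = 99)
  expect_equal(nrow(grid), 30)
  expect_equal(unique(table(grid$subject)), 3L)
  grid2 <- subject_sample_test(tab, models, n_per_subject = 3, seed = 99)
  expect_identical(grid, grid2)

  acc <- attr(grid, "accuracy")
  for (nm in names(models)) {
    cm <- confusion_matrix(grid$actual, grid[[nm]])
    expect_equal(unname(acc[nm]), cm$accuracy)
  }
  expect_error(subject_sample_test(tab, models, n_per_subject = 30), "need 30")
})
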