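#' Baseline classifier specification
#'
#' The six reference classifiers the neural networks are compared against:
#' k-nearest neighbours, a shallow ("simple") and a deep ("complex") decision
#' tree, and support vector machines with the inhomogeneous polynomial kernel
#' `K(xi, xj) = (xi' xj + 1)^rho` at degrees 1 (linear), 2 (quadratic) and
#' 3 (cubic).
#'
#' Hyperparameter defaults mirror the common presets of desktop
#' classification toolboxes: `k = 5` neighbours; the simple tree is depth-
#' limited to 2 (at most 3 splits) while the complex tree grows effectively
#' unpruned; SVM box constraint 1.
#'
#' @param kind One of `"knn"`, `"tree_simple"`, `"tree_complex"`,
#'   `"svm_linear"`, `"svm_quadratic"`, `"svm_cubic"`.
#' @param k Neighbour count for KNN.
#' @param cost SVM box constraint.
#' @return Object of class `baseline_spec`.
#' @export
baseline_spec <- function(kind, k = 5, cost = 1) {
  kinds <- c("knn", "tree_simple", "tree_complex",
             "svm_linear", "svm_quadratic", "svm_cubic")
  if (!kind %in% kinds) {
    stop_cfg("unknown baseline kind '%s' (expected one of %s)", kind,
             paste(kinds, collapse = ", "))
  }
  degree <- c(svm_linear = 1, svm_quadratic = 2, svm_cubic = 3)[kind]
  structure(list(kind = kind, k = k, cost = cost,
                 degree = unname(degree)),
            class = "baseline_spec")
}

#' Fit a baseline classifier on a feature table
#'
#' KNN stores the training set (prediction is the vote of the `k` nearest
#' training points); trees are fit with recursive partitioning; SVMs with the
#' exact polynomial kernel `(xi' xj + 1)^rho` on the raw (unscaled) features.
#'
#' @param spec A [baseline_spec()] or a kind string accepted by it.
#' @param table Training `feature_table` containing both classes.
#' @return Object of class `bluff_baseline` supporting [predict()].
#' @export
train_baseline <- function(spec, table) {
  if (is.character(spec)) spec <- baseline_spec(spec)
  stopifnot(inherits(spec, "baseline_spec"))
  check_label(table$label)
  if (length(unique(table$label)) < 2) {
    stop_cfg("training data holds a single class; need both lie and truth")
  }
  x <- as.matrix(table[, c("sm", "ss")])
  y <- factor(table$label, levels = c("lie", "truth"))
  fit <- switch(spec$kind,
    knn = list(x = x, y = y, k = spec$k),
    tree_simple = rpart::rpart(
      label ~ sm + ss, data = as.data.frame(table), method = "class",
      control = rpart::rpart.control(maxdepth = 2, minsplit = 5, cp = 0.01)),
    tree_complex = rpart::rpart(
      label ~ sm + ss, data = as.data.frame(table), method = "class",
      control = rpart::rpart.control(maxdepth = 30, minsplit = 4,
                                     minbucket = 2, cp = 0)),
    # svm_* share one code path
    {
      e1071::svm(x, y, kernel = "polynomial", degree = spec$degree,
                 gamma = 1, coef0 = 1, cost = spec$cost, scale = FALSE)
    }
  )
  obj <- structure(list(spec = spec, fit = fit), class = "bluff_baseline")
  if (grepl("^svm", spec$kind)) {
    # orient decision values so larger = more lie-like
    dv <- attr(stats::predict(fit, x, decision.values = TRUE),
               "decision.values")[, 1]
    obj$svm_sign <- if (stats::cor(dv, as.numeric(y == "lie")) >= 0) 1 else -1
  }
  obj
}

#' Predict labels and lie scores from a fitted baseline
#'
#' Scores are continuous lie propensities usable for ROC analysis: the
#' neighbour lie-vote fraction (KNN), the leaf lie probability (trees), or a
#' logistic squash of the oriented SVM decision value.
#'
#' @param object A `bluff_baseline`.
#' @param newdata `feature_table` or matrix with `sm`, `ss` columns.
#' @param ... Unused.
#' @return Data frame with columns `label` and `score`.
#' @export
predict.bluff_baseline <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) as.matrix(newdata[, c("sm", "ss")]) else newdata
  kind <- object$spec$kind
  if (kind == "knn") {
    pred <- class::knn(object$fit$x, x, object$fit$y, k = object$fit$k,
                       prob = TRUE)
    win <- attr(pred, "prob")
    score <- ifelse(pred == "lie", win, 1 - win)
    label <- as.character(pred)
  } else if (grepl("^tree", kind)) {
    nd <- as.data.frame(x)
    colnames(nd) <- c("sm", "ss")
    prob <- stats::predict(object$fit, nd, type = "prob")
    score <- if ("lie" %in% colnames(prob)) prob[, "lie"] else numeric(nrow(nd))
    label <- ifelse(score > 0.5, "lie", "truth")
  } else {
    dv <- attr(stats::predict(object$fit, x, decision.values = TRUE),
               "decision.values")[, 1]
    dv <- object$svm_sign * dv
    score <- stats::plogis(dv)
    label <- ifelse(dv > 0, "lie", "truth")
  }
  data.frame(label = label, score = as.numeric(score),
             stringsAsFactors = FALSE)
}

#' All classifier kinds known to the pipeline
#' @return Character vector of the three network and six baseline kinds.
#' @export
classifier_kinds <- function() {
  c("m1", "m2", "m3", "knn", "tree_simple", "tree_complex",
    "svm_linear", "svm_quadratic", "svm_cubic")
}

#' Train any pipeline classifier by kind
#'
#' Dispatches to [train_mlp()] (kinds `m1`, `m2`, `m3`, `m3_wide`) or
#' [train_baseline()]; all returned objects share the
#' `predict(object, newdata)` contract returning `label` and `score`.
#'
#' @param kind Classifier kind (see [classifier_kinds()]).
#' @param table Training `feature_table`.
#' @param cfg [train_config()]; used by the networks (its seed also seeds
#'   initialization).
#' @param val_table Optional validation table for network histories.
#' @return A trained classifier.
#' @export
train_classifier <- function(kind, table, cfg = train_config(),
                             val_table = NULL) {
  if (kind %in% c("m1", "m2", "m3", "m3_wide")) {
    train_mlp(init_mlp(mlp_spec(kind), seed = cfg$seed), table, cfg, val_table)
  } else {
    train_baseline(kind, table)
  }
}
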