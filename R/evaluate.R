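#' Confusion matrix for lie/truth predictions
#'
#' Counts with lie as the positive class: `tp` lies called lies, `fn` lies
#' called truths, `fp` truths called lies, `tn` truths called truths.
#'
#' @param actual Character vector of true labels (`lie`/`truth`).
#' @param predicted Character vector of predicted labels, same length.
#' @return Object of class `confusion_matrix`: list with `tp`, `fp`, `tn`,
#'   `fn`, `n` and `accuracy` (percent).
#' @examples
#' confusion_matrix(c("lie", "truth"), c("lie", "lie"))
#' @export
confusion_matrix <- function(actual, predicted) {
  if (length(actual) != length(predicted)) {
    stop_cfg("actual (%d) and predicted (%d) lengths differ",
             length(actual), length(predicted))
  }
  check_label(actual)
  check_label(predicted)
  tp <- sum(actual == "lie" & predicted == "lie")
  fn <- sum(actual == "lie" & predicted == "truth")
  fp <- sum(actual == "truth" & predicted == "lie")
  tn <- sum(actual == "truth" & predicted == "truth")
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn, n = length(actual),
                 accuracy = 100 * (tp + tn) / length(actual)),
            class = "confusion_matrix")
}

#' True- and false-positive rates
#'
#' `tpr = tp / (tp + fn)` (recall on lies), `fpr = fp / (fp + tn)`.
#'
#' @param cm A [confusion_matrix()].
#' @return Named numeric vector `c(tpr = , fpr = )`.
#' @export
tpr_fpr <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$tp + cm$fn == 0 || cm$fp + cm$tn == 0) {
    stop_cfg("rates undefined: one class is empty (lies = %d, truths = %d)",
             cm$tp + cm$fn, cm$fp + cm$tn)
  }
  c(tpr = cm$tp / (cm$tp + cm$fn), fpr = cm$fp / (cm$fp + cm$tn))
}

#' ROC curve from continuous lie scores
#'
#' Sweeps a decision threshold over every distinct score (tied scores share
#' one threshold), collecting `(fpr, tpr)` points anchored at `(0, 0)` and
#' `(1, 1)`.  Both coordinates are monotone non-decreasing along the curve.
#'
#' @param scores Finite numeric scores; larger means more lie-like.
#' @param actual True labels (`lie`/`truth`), both classes present.
#' @return Object of class `roc_curve`: list with `points` (data frame
#'   `threshold`, `fpr`, `tpr`) and `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, actual) {
  check_label(actual)
  if (any(!is.finite(scores))) stop_cfg("scores must be finite")
  if (length(scores) != length(actual)) stop_cfg("scores/labels length mismatch")
  n_pos <- sum(actual == "lie")
  n_neg <- sum(actual == "truth")
  if (n_pos == 0 || n_neg == 0) {
    stop_cfg("ROC needs both classes (lies = %d, truths = %d)", n_pos, n_neg)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  pos <- actual[ord] == "lie"
  # cumulative counts at each tie-group boundary
  grp_last <- which(c(s[-1] != s[-length(s)], TRUE))
  tp <- cumsum(pos)[grp_last]
  fp <- cumsum(!pos)[grp_last]
  pts <- data.frame(
    threshold = c(Inf, s[grp_last]),
    fpr = c(0, fp / n_neg),
    tpr = c(0, tp / n_pos)
  )
  structure(list(points = pts, n_pos = n_pos, n_neg = n_neg),
            class = "roc_curve")
}

#' Area under an ROC curve
#'
#' Trapezoidal area from `(0,0)` to `(1,1)`.  With the tie-grouped sweep of
#' [roc_curve()] this equals the probability that a random lie outscores a
#' random truth, ties counting one half (the Mann-Whitney identity).
#'
#' @param curve A [roc_curve()].
#' @return Numeric scalar in `[0, 1]`.
#' @export
auc <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  p <- curve$points
  sum(diff(p$fpr) * (p$tpr[-1] + p$tpr[-nrow(p)]) / 2)
}

#' Stratified train/validation/test split
#'
#' Shuffles within each label stratum and allocates rows to the three parts
#' by cumulative-fraction rounding, so part sizes are exact when the
#' arithmetic is (e.g. 200 rows at 0.6/0.2/0.2 gives 120/40/40) and every
#' part's lie fraction stays within one sample of the global fraction.
#'
#' @param table A `feature_table`.
#' @param fractions Length-3 proportions summing to 1.
#' @param seed Integer seed.
#' @return Named list of three disjoint `feature_table`s: `train`, `val`,
#'   `test`.
#' @export
split_train_val_test <- function(table, fractions = c(0.6, 0.2, 0.2),
                                 seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8) {
    stop_cfg("split fractions must sum to 1, got %g", sum(fractions))
  }
  check_label(table$label)
  assign_part <- function(n) {
    # cumulative rounding: part sizes differ from n*frac by < 1
    bounds <- round(cumsum(fractions) * n)
    rep.int(1:3, times = diff(c(0, bounds)))
  }
  part <- integer(nrow(table))
  with_seed(seed, {
    for (lab in unique(table$label)) {
      idx <- which(table$label == lab)
      part[idx[sample.int(length(idx))]] <- assign_part(length(idx))
    }
  })
  out <- lapply(1:3, function(p) {
    sub <- table[part == p, , drop = FALSE]
    rownames(sub) <- NULL
    sub
  })
  names(out) <- c("train", "val", "test")
  out
}

#' Evaluate one classifier on one stratified split
#'
#' Trains on the 60% part and reports the confusion matrix, accuracy, ROC and
#' AUC on the held-out test part (the validation part is passed to network
#' training for its history only; no model selection is performed).
#'
#' @param kind Classifier kind (see [classifier_kinds()]).
#' @param table Full `feature_table`.
#' @param cfg [train_config()] (fractions, epochs, seed).
#' @param split_seed Seed for the split; defaults to `cfg$seed`.
#' @return List with `kind`, `cm`, `accuracy`, `roc`, `auc`, `model`.
#' @export
evaluate_split <- function(kind, table, cfg = train_config(),
                           split_seed = NULL) {
  parts <- split_train_val_test(table, cfg$fractions,
                                seed = split_seed %||% cfg$seed)
  model <- train_classifier(kind, parts$train, cfg, val_table = parts$val)
  pred <- stats::predict(model, parts$test)
  cm <- confusion_matrix(parts$test$label, pred$label)
  roc <- roc_curve(pred$score, parts$test$label)
  list(kind = kind, cm = cm, accuracy = cm$accuracy, roc = roc,
       auc = auc(roc), model = model)
}

#' Leave-one-subject-out evaluation
#'
#' One fold per subject: train on the other subjects' trials, test on the
#' held-out subject, so reported accuracy reflects generalization to unseen
#' people.  No trial of the test subject ever enters training.
#'
#' @param table `feature_table` with at least two subjects.
#' @param kind Classifier kind.
#' @param cfg [train_config()].
#' @return List with `per_subject` (data frame `subject`, `n`, `accuracy`)
#'   and `mean_accuracy` (percent, unweighted mean over folds).
#' @export
loso_evaluate <- function(table, kind, cfg = train_config()) {
  subjects <- sort(unique(table$subject))
  if (length(subjects) < 2) stop_cfg("LOSO needs >= 2 subjects")
  fold_seeds <- derive_seeds(cfg$seed, length(subjects))
  rows <- lapply(seq_along(subjects), function(i) {
    s <- subjects[i]
    train <- table[table$subject != s, , drop = FALSE]
    test <- table[table$subject == s, , drop = FALSE]
    fold_cfg <- cfg
    fold_cfg$seed <- fold_seeds[i]
    model <- train_classifier(kind, train, fold_cfg)
    pred <- stats::predict(model, test)
    data.frame(subject = s, n = nrow(test),
               accuracy = 100 * mean(pred$label == test$label))
  })
  per_subject <- do.call(rbind, rows)
  list(per_subject = per_subject,
       mean_accuracy = mean(per_subject$accuracy))
}

#' Per-subject sample test across trained classifiers
#'
#' Draws `n_per_subject` trials from each subject and tabulates every
#' classifier's prediction next to the actual label — the robustness
#' spot-check grid reported alongside overall accuracies.
#'
#' @param table `feature_table`; every subject needs at least
#'   `n_per_subject` rows.
#' @param classifiers Named list of trained classifiers (any mix of networks
#'   and baselines).
#' @param n_per_subject Trials sampled per subject (default 3).
#' @param seed Integer seed for the draw.
#' @return Data frame `subject`, `sample`, `actual`, then one prediction
#'   column per classifier; attribute `"accuracy"` holds each classifier's
#'   percent agreement with `actual`.
#' @export
subject_sample_test <- function(table, classifiers, n_per_subject = 3,
                                seed = 1L) {
  stopifnot(length(names(classifiers)) == length(classifiers))
  subjects <- sort(unique(table$subject))
  picked <- with_seed(seed, {
    do.call(rbind, lapply(subjects, function(s) {
      rows <- table[table$subject == s, , drop = FALSE]
      if (nrow(rows) < n_per_subject) {
        stop_cfg("subject %s has %d trials; need %d", s, nrow(rows),
                 n_per_subject)
      }
      sub <- rows[sample.int(nrow(rows), n_per_subject), , drop = FALSE]
      sub$sample <- seq_len(n_per_subject)
      sub
    }))
  })
  grid <- data.frame(subject = picked$subject, sample = picked$sample,
                     actual = picked$label, stringsAsFactors = FALSE)
  acc <- numeric(0)
  for (nm in names(classifiers)) {
    pred <- stats::predict(classifiers[[nm]], picked)
    grid[[nm]] <- pred$label
    acc[nm] <- 100 * mean(pred$label == grid$actual)
  }
  attr(grid, "accuracy") <- acc
  grid
}
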