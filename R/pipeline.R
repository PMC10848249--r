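#' Pipeline configuration
#'
#' Bundles the stage configurations and a single master seed that is fanned
#' out deterministically to every stochastic stage (simulation, splitting,
#' training, sample draws), so any stage can be re-run in isolation and still
#' reproduce the full run.
#'
#' @param sim [sim_config()].
#' @param constants [optical_constants()].
#' @param filter [filter_spec()].
#' @param train [train_config()].
#' @param classifiers Character vector of classifier kinds to evaluate
#'   (default all nine).
#' @param out_dir Optional directory for persisted artifacts.
#' @param seed Master integer seed (overrides the stage seeds).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            constants = optical_constants(),
                            filter = filter_spec(),
                            train = train_config(),
                            classifiers = classifier_kinds(),
                            out_dir = NULL,
                            seed = 1L) {
  unknown <- setdiff(classifiers, c(classifier_kinds(), "m3_wide"))
  if (length(unknown) > 0) {
    stop_cfg("unknown classifier kind(s): %s", paste(unknown, collapse = ", "))
  }
  structure(list(sim = sim, constants = constants, filter = filter,
                 train = train, classifiers = classifiers,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full simulate-convert-classify-evaluate pipeline
#'
#' Stages, in order: simulate the labeled bluff-game dataset; convert raw
#' intensities to hemoglobin via the modified Beer-Lambert law; low-pass
#' filter, channel-average and epoch the claim windows; build the SM/SS
#' feature table; train and evaluate every requested classifier on
#' `train$repeats` independent stratified splits; run the per-subject sample
#' test with all classifiers from the first split.  When `out_dir` is set,
#' every intermediate artifact is written there together with a manifest
#' recording the configuration, its checksum, and the derived stage seeds.
#'
#' @param config A [pipeline_config()].
#' @return List of class `eval_report`: `features`, `results` (per-classifier
#'   data frame with mean/per-repeat accuracy and AUC), `sample_test`,
#'   `sample_test_accuracy`, `seeds`, `config`.
#' @export
run_all <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- derive_seeds(config$seed, 4L,
                        labels = c("simulate", "split", "train", "sample"))
  sim_cfg <- config$sim
  sim_cfg$seed <- seeds[["simulate"]]
  dataset <- simulate_experiment(sim_cfg, config$constants)
  features <- extract_features(dataset, config$filter)

  split_seeds <- derive_seeds(seeds[["split"]], config$train$repeats)
  train_seeds <- derive_seeds(seeds[["train"]], config$train$repeats)
  results <- list()
  first_models <- list()
  for (kind in config$classifiers) {
    accs <- numeric(config$train$repeats)
    aucs <- numeric(config$train$repeats)
    for (r in seq_len(config$train$repeats)) {
      cfg_r <- config$train
      cfg_r$seed <- train_seeds[r]
      ev <- evaluate_split(kind, features, cfg_r, split_seed = split_seeds[r])
      accs[r] <- ev$accuracy
      aucs[r] <- ev$auc
      if (r == 1) first_models[[kind]] <- ev$model
    }
    results[[kind]] <- data.frame(
      kind = kind, mean_accuracy = mean(accs), best_accuracy = max(accs),
      mean_auc = mean(aucs), t(accs),
      stringsAsFactors = FALSE
    )
  }
  results <- do.call(rbind, results)
  rownames(results) <- NULL
  names(results) <- sub("^X", "acc_run", names(results))

  sample_grid <- subject_sample_test(features, first_models,
                                     seed = seeds[["sample"]])
  report <- structure(
    list(features = features, results = results, sample_test = sample_grid,
         sample_test_accuracy = attr(sample_grid, "accuracy"),
         seeds = seeds, config = config),
    class = "eval_report"
  )
  if (!is.null(config$out_dir)) persist_report(report, dataset, config)
  report
}

persist_report <- function(report, dataset, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_features_csv(report$features, file.path(config$out_dir, "features.csv"))
  write_events_tsv(dataset$schedule, config$sim,
                   file.path(config$out_dir, "events.tsv"))
  utils::write.csv(report$results, file.path(config$out_dir, "results.csv"),
                   row.names = FALSE)
  utils::write.csv(report$sample_test,
                   file.path(config$out_dir, "sample_test.csv"),
                   row.names = FALSE)
  cfg_path <- file.path(config$out_dir, "config.json")
  cfg_json <- list(
    sim = unclass(config$sim), filter = unclass(config$filter),
    train = unclass(config$train), classifiers = config$classifiers,
    seed = config$seed, stage_seeds = as.list(report$seeds)
  )
  jsonlite::write_json(cfg_json, cfg_path, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    config_md5 = unname(tools::md5sum(cfg_path)),
    files = list.files(config$out_dir),
    seed = config$seed,
    stage_seeds = as.list(report$seeds)
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(NULL)
}

#' Recompute per-classifier accuracies from a printed prediction grid
#'
#' Reads a per-sample prediction table (columns `subject`, `sample`,
#' `actual`, then one column per classifier) and recomputes each
#' classifier's accuracy against the actual labels.  The package ships the
#' published 30-sample grid as
#' `system.file("extdata", "table2_predictions.csv", package = "fnirsbluff")`.
#' Accuracies are invariant to row order.
#'
#' @param path CSV fixture path; default the shipped grid.
#' @return Data frame `classifier`, `accuracy` (percent, one decimal
#'   resolution is meaningful at n = 30).
#' @examples
#' check_table2()
#' @export
check_table2 <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "table2_predictions.csv",
                        package = "fnirsbluff")
  }
  grid <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("subject", "sample", "actual")
  if (!all(needed %in% names(grid))) {
    stop_cfg("fixture must have columns %s", paste(needed, collapse = ", "))
  }
  check_label(grid$actual)
  cls <- setdiff(names(grid), needed)
  if (length(cls) == 0) stop_cfg("fixture has no classifier columns")
  acc <- vapply(cls, function(cl) {
    check_label(grid[[cl]])
    100 * mean(grid[[cl]] == grid$actual)
  }, numeric(1))
  data.frame(classifier = cls, accuracy = unname(acc),
             stringsAsFactors = FALSE)
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Bluff-game fNIRS lie-detection evaluation\n")
  cat(sprintf("  trials: %d  (%d subjects)\n", nrow(x$features),
              length(unique(x$features$subject))))
  cat(sprintf("  repeats per classifier: %d\n",
              x$config$train$repeats))
  print(x$results[, c("kind", "mean_accuracy", "best_accuracy", "mean_auc")],
        row.names = FALSE, digits = 4)
  invisible(x)
}
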