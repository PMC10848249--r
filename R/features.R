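#' Signal mean of a claim-window epoch
#'
#' Arithmetic mean of the epoch's HbO samples (umol/L) — one of the two
#' features driving lie/truth classification.
#'
#' @param epoch A `trial_epoch`.
#' @return Numeric scalar in umol/L.
#' @export
signal_mean <- function(epoch) {
  stopifnot(inherits(epoch, "trial_epoch"))
  if (length(epoch$hbo) < 1) stop_cfg("empty epoch")
  mean(epoch$hbo)
}

#' Signal slope of a claim-window epoch
#'
#' Ordinary-least-squares slope of HbO against time in seconds over the
#' claim window (umol/L per second).  The hemodynamic response is still
#' rising during the 5 s claim, so the slope separates strong (lie) from weak
#' (truth) responses.
#'
#' @param epoch A `trial_epoch` with at least two distinct timestamps.
#' @return Numeric scalar in umol/L/s.
#' @export
signal_slope <- function(epoch) {
  stopifnot(inherits(epoch, "trial_epoch"))
  t <- epoch$time_s
  if (length(t) < 2) stop_cfg("need >= 2 samples for a slope, got %d", length(t))
  tc <- t - mean(t)
  denom <- sum(tc^2)
  if (denom == 0) stop_cfg("zero time variance in epoch")
  sum(tc * (epoch$hbo - mean(epoch$hbo))) / denom
}

#' Assemble the per-trial feature table
#'
#' One row per epoch with the signal mean (`sm`), signal slope (`ss`) and the
#' lie/truth label.  Rows are ordered by subject then session.  Features are
#' not standardized by default (SM and SS are already on comparable
#' micromolar scales); `zscore = TRUE` standardizes each feature column, which
#' matters for scale-sensitive baselines such as KNN and kernel SVMs.
#'
#' @param epochs List of `trial_epoch` objects.
#' @param zscore Standardize the `sm`/`ss` columns (default `FALSE`).
#' @return Data frame `subject, session, sm, ss, label`, class
#'   `c("feature_table", "data.frame")`.
#' @export
build_feature_table <- function(epochs, zscore = FALSE) {
  if (length(epochs) == 0) stop_cfg("no epochs supplied")
  tab <- do.call(rbind, lapply(epochs, function(e) {
    data.frame(subject = e$subject, session = e$session,
               sm = signal_mean(e), ss = signal_slope(e),
               label = e$label, stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(tab[, c("subject", "session")])) {
    stop_cfg("duplicate (subject, session) keys in epoch list")
  }
  check_label(tab$label)
  if (any(!is.finite(tab$sm)) || any(!is.finite(tab$ss))) {
    stop_cfg("non-finite feature values")
  }
  tab <- tab[order(tab$subject, tab$session), , drop = FALSE]
  rownames(tab) <- NULL
  if (zscore) {
    tab$sm <- as.numeric(scale(tab$sm))
    tab$ss <- as.numeric(scale(tab$ss))
  }
  class(tab) <- c("feature_table", "data.frame")
  tab
}

#' Full preprocessing chain: dataset to feature table
#'
#' Converts every subject's raw recording to hemoglobin, low-pass filters,
#' averages the channels, epochs the claim windows and assembles the feature
#' table.  The optical-density baseline window is the first card-arrangement
#' phase `[0, arrange_s)`.
#'
#' @param dataset A `bluff_dataset` from [simulate_experiment()], or a list
#'   with elements `recordings`, `schedule`, `config`, `constants`.
#' @param fspec [filter_spec()] to apply.
#' @param zscore Passed to [build_feature_table()].
#' @return A `feature_table`.
#' @export
extract_features <- function(dataset, fspec = filter_spec(), zscore = FALSE) {
  cfg <- dataset$config
  epochs <- list()
  for (rec in dataset$recordings) {
    hemo <- convert_recording(rec, dataset$constants,
                              baseline_s = c(0, cfg$arrange_s))
    hemo <- lowpass_filter(hemo, fspec)
    avg <- average_channels(hemo)
    epochs <- c(epochs, epoch_trials(avg, dataset$schedule, cfg$claim_s))
  }
  build_feature_table(epochs, zscore = zscore)
}
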