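#' Write a raw-intensity recording as wide TSV
#'
#' Columns: `time_s`, then `ch01_w1 ch01_w2 ... chNN_w2` (wavelength order
#' 640 nm, 910 nm), one row per sample.
#'
#' @param recording An `intensity_recording`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_intensity_tsv <- function(recording, path) {
  stopifnot(inherits(recording, "intensity_recording"))
  df <- data.frame(time_s = recording$time_s, recording$intensity,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a wide-TSV intensity recording
#'
#' @param path TSV written by [write_intensity_tsv()] (or any file in that
#'   dialect).
#' @param subject Optional subject id to attach.
#' @param fs_hz Sampling rate; inferred from the median timestamp step when
#'   `NULL`.
#' @return An `intensity_recording`.
#' @export
read_intensity_tsv <- function(path, subject = NULL, fs_hz = NULL) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (!"time_s" %in% names(df)) stop_cfg("missing time_s column in %s", path)
  inten <- as.matrix(df[, setdiff(names(df), "time_s"), drop = FALSE])
  if (is.null(fs_hz)) fs_hz <- 1 / stats::median(diff(df$time_s))
  structure(
    list(subject = subject, fs_hz = fs_hz, time_s = df$time_s,
         intensity = inten),
    class = "intensity_recording"
  )
}

#' Write the experiment events TSV
#'
#' Long-format phase listing: columns `subject session onset_s duration_s
#' phase label` with one arrange, claim and response row per session; the
#' lie/truth label is set only on claim rows (`n/a` elsewhere).
#'
#' @param schedule An `experiment_schedule`.
#' @param config The [sim_config()] supplying phase durations.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(schedule, config, path) {
  rows <- do.call(rbind, lapply(seq_len(nrow(schedule)), function(i) {
    s <- schedule[i, ]
    data.frame(
      subject = s$subject, session = s$session,
      onset_s = c(s$onset_s, s$claim_onset_s, s$claim_onset_s + config$claim_s),
      duration_s = c(config$arrange_s, config$claim_s, config$response_s),
      phase = c("arrange", "claim", "response"),
      label = c("n/a", s$label, "n/a"),
      stringsAsFactors = FALSE
    )
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an events TSV back into a schedule
#'
#' @param path Events TSV (see [write_events_tsv()]).
#' @return An `experiment_schedule` reconstructed from the claim rows.
#' @export
read_events_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  claims <- df[df$phase == "claim", , drop = FALSE]
  sess <- df[df$phase == "arrange", c("subject", "session", "onset_s")]
  out <- merge(sess, claims[, c("subject", "session", "onset_s", "label")],
               by = c("subject", "session"), suffixes = c("", "_claim"))
  names(out)[names(out) == "onset_s_claim"] <- "claim_onset_s"
  out <- out[order(out$subject, out$session), ]
  rownames(out) <- NULL
  class(out) <- c("experiment_schedule", "data.frame")
  out
}

#' Write a hemoglobin series as TSV
#'
#' Columns `time_s`, `ch01_hbo`, `ch01_hbr`, ... in umol/L.
#' @param series A `hemo_series`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_hemo_tsv <- function(series, path) {
  stopifnot(inherits(series, "hemo_series"))
  nch <- ncol(series$hbo)
  df <- data.frame(time_s = series$time_s)
  for (ch in seq_len(nch)) {
    df[[sprintf("ch%02d_hbo", ch)]] <- series$hbo[, ch]
    df[[sprintf("ch%02d_hbr", ch)]] <- series$hbr[, ch]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a hemoglobin-series TSV
#' @param path TSV written by [write_hemo_tsv()].
#' @param subject Optional subject id.
#' @param fs_hz Sampling rate; inferred from timestamps when `NULL`.
#' @return A `hemo_series`.
#' @export
read_hemo_tsv <- function(path, subject = NULL, fs_hz = NULL) {
  df <- utils::read.delim(path, check.names = FALSE)
  hbo_cols <- grep("_hbo$", names(df), value = TRUE)
  hbr_cols <- grep("_hbr$", names(df), value = TRUE)
  if (is.null(fs_hz)) fs_hz <- 1 / stats::median(diff(df$time_s))
  hbo <- as.matrix(df[, hbo_cols, drop = FALSE])
  hbr <- as.matrix(df[, hbr_cols, drop = FALSE])
  colnames(hbo) <- sub("_hbo$", "", hbo_cols)
  colnames(hbr) <- sub("_hbr$", "", hbr_cols)
  structure(list(subject = subject, fs_hz = fs_hz, time_s = df$time_s,
                 hbo = hbo, hbr = hbr),
            class = "hemo_series")
}

#' Write / read the feature table CSV
#'
#' Plain CSV `subject,session,sm,ss,label`, rows ordered by subject then
#' session.
#' @param table A `feature_table`.
#' @param path Output file.
#' @return `path` invisibly (write) or a `feature_table` (read).
#' @export
write_features_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_label(tab$label)
  class(tab) <- c("feature_table", "data.frame")
  tab
}

#' Serialize a trained MLP to JSON
#'
#' The file holds the architecture, every layer's weights and biases, the
#' initialization seed and the full training history, and round-trips
#' losslessly through [load_model_json()].
#'
#' @param model A `bluff_mlp`.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
save_model_json <- function(model, path) {
  stopifnot(inherits(model, "bluff_mlp"))
  payload <- list(
    spec = list(name = model$spec$name, widths = model$spec$widths),
    seed = model$seed,
    weights = lapply(model$w, unclass),
    biases = model$b,
    center = model$center,
    scale = model$scale,
    history = model$history
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_model_json
#' @export
load_model_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- mlp_spec(widths = p$spec$widths)
  spec$name <- p$spec$name
  w <- lapply(p$weights, function(m) matrix(as.numeric(m), nrow = nrow(m)))
  b <- lapply(p$biases, as.numeric)
  hist <- if (is.null(p$history) || length(p$history) == 0) NULL
          else as.data.frame(p$history)
  model <- structure(list(spec = spec, w = w, b = b, seed = as.integer(p$seed),
                          history = hist),
                     class = "bluff_mlp")
  if (!is.null(p$center)) {
    model$center <- unlist(p$center)
    model$scale <- unlist(p$scale)
  }
  model
}
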