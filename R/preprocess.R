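#' Low-pass filter specification
#'
#' A second-order low-pass Butterworth design with 0.15 Hz cutoff removes
#' cardiac (~1.1 Hz) and respiratory (~0.3 Hz) oscillations while passing the
#' slow hemodynamic response.  Zero-phase (forward-backward) application is
#' the default so claim-window features are not delayed; a causal single-pass
#' mode is available for comparison.
#'
#' @param order Filter order (default 2).
#' @param cutoff_hz Cutoff frequency in Hz (default 0.15); must be below the
#'   Nyquist frequency of the series it is applied to.
#' @param zero_phase Apply forward-backward (`TRUE`, default) or causal.
#' @return Object of class `filter_spec`.
#' @export
filter_spec <- function(order = 2, cutoff_hz = 0.15, zero_phase = TRUE) {
  stopifnot(order >= 1, cutoff_hz > 0)
  structure(list(order = order, cutoff_hz = cutoff_hz, zero_phase = zero_phase),
            class = "filter_spec")
}

#' Low-pass filter a hemoglobin series
#'
#' Applies the Butterworth design in `spec` to every HbO and HbR channel.
#' The filter has unit DC gain, preserves series length, and is linear and
#' time-invariant.
#'
#' @param series A `hemo_series`.
#' @param spec A [filter_spec()].
#' @return Filtered `hemo_series` of identical shape.
#' @export
lowpass_filter <- function(series, spec = filter_spec()) {
  stopifnot(inherits(series, "hemo_series"), inherits(spec, "filter_spec"))
  nyq <- series$fs_hz / 2
  if (spec$cutoff_hz >= nyq) {
    stop_cfg("cutoff %g Hz is not below the Nyquist frequency %g Hz",
             spec$cutoff_hz, nyq)
  }
  if (any(!is.finite(series$hbo)) || any(!is.finite(series$hbr))) {
    stop_cfg("series contains non-finite values")
  }
  bf <- signal::butter(spec$order, spec$cutoff_hz / nyq, type = "low")
  # forward-backward pass on an odd-reflection extension of the series, so
  # start-up transients decay inside the padding rather than inside the data
  pad <- ceiling(10 * series$fs_hz / spec$cutoff_hz)
  apply_fn <- if (spec$zero_phase) {
    function(x) {
      n <- length(x)
      p <- min(n - 1, pad)
      ext <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
      signal::filtfilt(bf, ext)[(p + 1):(p + n)]
    }
  } else {
    function(x) as.numeric(signal::filter(bf, x))
  }
  out <- series
  out$hbo <- apply(series$hbo, 2, apply_fn)
  out$hbr <- apply(series$hbr, 2, apply_fn)
  dimnames(out$hbo) <- dimnames(series$hbo)
  dimnames(out$hbr) <- dimnames(series$hbr)
  out
}

#' Average all channels into a single HbO series
#'
#' The classification stage works on the channel-averaged HbO signal (the
#' probe covers one prefrontal patch, and averaging suppresses independent
#' channel noise).
#'
#' @param series A `hemo_series` with at least one channel.
#' @return An `hbo_series`: `list(subject, fs_hz, time_s, hbo)` with `hbo` a
#'   plain numeric vector.
#' @export
average_channels <- function(series) {
  stopifnot(inherits(series, "hemo_series"))
  if (ncol(series$hbo) < 1) stop_cfg("no channels to average")
  structure(
    list(subject = series$subject, fs_hz = series$fs_hz,
         time_s = series$time_s, hbo = rowMeans(series$hbo)),
    class = "hbo_series"
  )
}

#' Cut claim-window epochs out of the averaged HbO series
#'
#' Extracts, for every scheduled session, the samples whose timestamps fall in
#' the half-open claim window `[claim_onset, claim_onset + claim_s)`; the
#' session's lie/truth label travels with the epoch.  At the 3.8 Hz
#' acquisition rate a 5 s window holds 19 samples.
#'
#' @param series An `hbo_series` from [average_channels()].
#' @param schedule An `experiment_schedule`; rows for other subjects are
#'   ignored when the series carries a subject id.
#' @param claim_s Claim-window duration in seconds (default 5).
#' @return List of `trial_epoch` objects:
#'   `list(subject, session, label, time_s, hbo)`.
#' @export
epoch_trials <- function(series, schedule, claim_s = 5) {
  stopifnot(inherits(series, "hbo_series"))
  rows <- schedule
  if (!is.null(series$subject)) {
    rows <- schedule[schedule$subject == series$subject, , drop = FALSE]
  }
  if (nrow(rows) == 0) stop_cfg("schedule holds no sessions for this subject")
  t_end <- series$time_s[length(series$time_s)]
  lapply(seq_len(nrow(rows)), function(i) {
    on <- rows$claim_onset_s[i]
    if (on > t_end) {
      stop_cfg("claim window of subject %s session %d starts at %g s, after the recording ends (%g s)",
               rows$subject[i], rows$session[i], on, t_end)
    }
    keep <- series$time_s >= on - 1e-9 & series$time_s < on + claim_s - 1e-9
    if (sum(keep) < 2) {
      stop_cfg("claim window of subject %s session %d holds fewer than 2 samples",
               rows$subject[i], rows$session[i])
    }
    structure(
      list(subject = rows$subject[i], session = rows$session[i],
           label = rows$label[i], time_s = series$time_s[keep],
           hbo = series$hbo[keep]),
      class = "trial_epoch"
    )
  })
}
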