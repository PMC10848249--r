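# Small configurations used across test files.

# noise-free configuration: only the event responses remain
quiet_config <- function(n_subjects = 1, n_sessions = 4, seed = 2,
                         min_lies = 0, ...) {
  sim_config(n_subjects = n_subjects, n_sessions = n_sessions,
             min_lies = min_lies, seed = seed,
             noise_cardiac_uM = 0, noise_resp_uM = 0, noise_mayer_uM = 0,
             noise_drift_uM_s = 0, noise_white_uM = 0, ...)
}

# balanced null configuration: no lie/truth amplitude difference
null_config <- function(seed = 1, ...) {
  sim_config(lie_fraction = 0.5, amp_lie_uM = 0.9, amp_truth_uM = 0.9,
             seed = seed, ...)
}

# wide-margin linearly separable feature table
separable_table <- function(n_per_class = 30, gap = 4, seed = 1) {
  set.seed(seed)
  data.frame(
    subject = rep(1:2, each = n_per_class),
    session = seq_len(2 * n_per_class),
    sm = c(rnorm(n_per_class, -gap / 2, 0.2), rnorm(n_per_class, gap / 2, 0.2)),
    ss = c(rnorm(n_per_class, -gap / 2, 0.2), rnorm(n_per_class, gap / 2, 0.2)),
    label = rep(c("truth", "lie"), each = n_per_class),
    stringsAsFactors = FALSE
  )
}

# XOR-arranged clusters: not linearly separable, quadratic-kernel separable
xor_table <- function(n_per_corner = 12, seed = 4) {
  set.seed(seed)
  corners <- expand.grid(sm = c(-1, 1), ss = c(-1, 1))
  rows <- do.call(rbind, lapply(seq_len(nrow(corners)), function(i) {
    data.frame(
      sm = rnorm(n_per_corner, corners$sm[i], 0.15),
      ss = rnorm(n_per_corner, corners$ss[i], 0.15),
      label = if (corners$sm[i] * corners$ss[i] > 0) "lie" else "truth"
    )
  }))
  rows$subject <- 1
  rows$session <- seq_len(nrow(rows))
  rows
}

# a tiny epoch object for feature unit tests
make_epoch <- function(hbo, time_s = seq_along(hbo), label = "lie",
                       subject = 1, session = 1) {
  structure(list(subject = subject, session = session, label = label,
                 time_s = time_s, hbo = hbo),
            class = "trial_epoch")
}

# a hemo_series built directly from matrices
make_hemo <- function(hbo, hbr = -hbo / 3, fs_hz = 3.8, subject = 1) {
  n <- nrow(hbo)
  structure(list(subject = subject, fs_hz = fs_hz,
                 time_s = (seq_len(n) - 1) / fs_hz, hbo = hbo, hbr = hbr),
            class = "hemo_series")
}

# FFT amplitude at the bin nearest f_hz
fft_amplitude <- function(x, fs_hz, f_hz) {
  n <- length(x)
  sp <- Mod(stats::fft(x - mean(x))) / n * 2
  freqs <- (seq_len(n) - 1) * fs_hz / n
  sp[which.min(abs(freqs - f_hz))]
}
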