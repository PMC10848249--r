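#' Configuration of a simulated bluff-game fNIRS experiment
#'
#' Describes the experiment the simulator emulates: subjects play an
#' interactive bluff card game in sessions of ~30 s, each split into a 15 s
#' card-arrangement phase, a 5 s claim phase (the moment of lying or
#' truth-telling) and a 10 s response phase, while a 12-channel dual-wavelength
#' continuous-wave imager samples the forehead at ~3.8 Hz.  Claim events evoke
#' a canonical hemodynamic response whose HbO amplitude depends on the label,
#' on top of cardiac, respiratory and Mayer-wave oscillations, slow drift and
#' white noise.
#'
#' Default amplitudes (`amp_lie_uM` = 1.2, `amp_truth_uM` = 0.6,
#' `noise_white_uM` = 0.3 umol/L) put the default pipeline in the 80-90%
#' accuracy regime typical of two-feature HbO lie-truth classification; all
#' values are configurable.
#'
#' @param n_subjects Number of subjects (default 10).
#' @param n_sessions Sessions per subject (default 20).
#' @param session_s,arrange_s,claim_s,response_s Phase durations in seconds
#'   (defaults 30 / 15 / 5 / 10; the three phases must fit in the session).
#' @param fs_hz Sampling rate in Hz (default 3.8).  Must exceed twice the
#'   highest physiological noise frequency used.
#' @param n_channels Number of optode channels (default 12).
#' @param lie_fraction Probability a session is a lie (default 0.35).
#' @param min_lies Minimum lies per subject; the bluff deck forces at least
#'   4 unmatched-card lies (default 4).
#' @param amp_lie_uM,amp_truth_uM Peak HbO response amplitude (umol/L) for lie
#'   and truth claims.
#' @param hbr_ratio HbR event amplitude as a (negative) fraction of HbO
#'   (default -1/3).
#' @param noise_cardiac_uM,noise_resp_uM,noise_mayer_uM Amplitudes (umol/L) of
#'   sinusoidal physiological components at 1.1, 0.3 and 0.1 Hz.
#' @param noise_drift_uM_s Standard deviation of the per-channel linear drift
#'   slope (umol/L per second).
#' @param noise_white_uM Standard deviation of white sample noise (umol/L).
#' @param noise_phase_sd Phase-diffusion rate of the systemic oscillations in
#'   radians per square-root second (default 0.3): each sinusoid's phase
#'   performs a random walk, emulating the natural wander of heart rate,
#'   breathing and vasomotion, so oscillations decorrelate across sessions.
#' @param i0 Baseline detected intensity per wavelength (detector units, > 0).
#' @param seed Integer master seed.
#' @return Object of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_subjects = 2, n_sessions = 6, seed = 1)
#' sched <- generate_schedule(cfg)
#' table(sched$label)
#' @export
sim_config <- function(n_subjects = 10,
                       n_sessions = 20,
                       session_s = 30,
                       arrange_s = 15,
                       claim_s = 5,
                       response_s = 10,
                       fs_hz = 3.8,
                       n_channels = 12,
                       lie_fraction = 0.35,
                       min_lies = 4,
                       amp_lie_uM = 1.2,
                       amp_truth_uM = 0.6,
                       hbr_ratio = -1 / 3,
                       noise_cardiac_uM = 0.3,
                       noise_resp_uM = 0.15,
                       noise_mayer_uM = 0.10,
                       noise_drift_uM_s = 4e-4,
                       noise_white_uM = 0.3,
                       noise_phase_sd = 0.3,
                       i0 = 1000,
                       seed = 1L) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

# physiological center frequencies (Hz) of the sinusoidal noise components
.noise_freqs <- c(cardiac = 1.1, resp = 0.3, mayer = 0.1)

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (lie_fraction < 0 || lie_fraction > 1) {
      stop_cfg("lie_fraction must lie in [0, 1], got %g", lie_fraction)
    }
    if (arrange_s + claim_s + response_s > session_s + 1e-9) {
      stop_cfg("phase durations (%g s) exceed session_s (%g s)",
               arrange_s + claim_s + response_s, session_s)
    }
    if (fs_hz <= 2 * max(.noise_freqs)) {
      stop_cfg("fs_hz = %g must exceed twice the highest noise frequency (%g Hz)",
               fs_hz, max(.noise_freqs))
    }
    amps <- c(amp_lie_uM, amp_truth_uM, noise_cardiac_uM, noise_resp_uM,
              noise_mayer_uM, noise_drift_uM_s, noise_white_uM)
    if (any(amps < 0)) stop_cfg("all amplitudes must be >= 0")
    if (i0 <= 0) stop_cfg("baseline intensity i0 must be positive, got %g", i0)
    if (n_subjects < 1 || n_sessions < 1 || n_channels < 1) {
      stop_cfg("counts must be positive")
    }
    if (min_lies > n_sessions) stop_cfg("min_lies exceeds n_sessions")
  })
  invisible(cfg)
}

#' Generate the per-subject session schedule with lie/truth labels
#'
#' Sessions are contiguous and non-overlapping: session j of every subject
#' starts at `(j - 1) * session_s` and its claim phase starts `arrange_s`
#' later.  Labels are drawn independently as lie with probability
#' `lie_fraction`; because the bluff deck guarantees unmatched cards, any
#' subject drawn with fewer than `min_lies` lies has randomly chosen truth
#' sessions flipped until the minimum is met.
#'
#' @param config A [sim_config()].
#' @return Data frame with columns `subject`, `session`, `onset_s`,
#'   `claim_onset_s`, `label`; class `c("experiment_schedule", "data.frame")`.
#' @export
generate_schedule <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- derive_seeds(config$seed, config$n_subjects + 10L)
  sched <- lapply(seq_len(config$n_subjects), function(s) {
    labels <- with_seed(seeds[s], {
      lab <- ifelse(stats::runif(config$n_sessions) < config$lie_fraction,
                    "lie", "truth")
      deficit <- config$min_lies - sum(lab == "lie")
      if (deficit > 0) {
        truth_idx <- which(lab == "truth")
        flip <- truth_idx[sample.int(length(truth_idx), deficit)]
        lab[flip] <- "lie"
      }
      lab
    })
    data.frame(
      subject = s,
      session = seq_len(config$n_sessions),
      onset_s = (seq_len(config$n_sessions) - 1) * config$session_s,
      claim_onset_s = (seq_len(config$n_sessions) - 1) * config$session_s +
        config$arrange_s,
      label = labels,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, sched)
  class(out) <- c("experiment_schedule", "data.frame")
  out
}

#' Canonical double-gamma hemodynamic response function
#'
#' The field-standard HRF: a gamma density peaking at 6 s minus 1/6 of a gamma
#' density peaking at 16 s (the post-stimulus undershoot), both with unit
#' dispersion.  Used as the impulse response of every claim event; the
#' convolution with the claim boxcar is normalized to unit peak downstream so
#' that event amplitudes are expressed directly in umol/L.
#'
#' @param t_s Time points in seconds (response is zero for `t_s < 0`).
#' @return Numeric vector of HRF values.
#' @export
canonical_hrf <- function(t_s) {
  h <- stats::dgamma(t_s, shape = 6, rate = 1) -
    stats::dgamma(t_s, shape = 16, rate = 1) / 6
  h[t_s < 0] <- 0
  h
}

# HRF convolved with a claim-length boxcar on the acquisition grid,
# normalized to unit peak.  Support truncated at 32 s (the response and its
# undershoot are negligible beyond that).
event_kernel <- function(fs_hz, claim_s, support_s = 32) {
  t <- seq(0, support_s, by = 1 / fs_hz)
  h <- canonical_hrf(t)
  box <- rep(1, max(1L, floor(claim_s * fs_hz)))
  k <- stats::convolve(c(h, numeric(length(box))), rev(box), type = "open")
  k <- k[seq_len(length(t))]
  pk <- max(abs(k))
  if (pk == 0) return(k)
  k / pk
}

sim_time_grid <- function(config) {
  n <- floor(config$n_sessions * config$session_s * config$fs_hz)
  (seq_len(n) - 1) / config$fs_hz
}

#' Synthesize ground-truth hemoglobin concentration time courses
#'
#' For each subject, builds the noise-free event signal by placing the
#' unit-peak HRF-boxcar kernel at every claim onset scaled by `amp_lie_uM` or
#' `amp_truth_uM`, shared across all channels (the analysis averages channels,
#' so no spatial structure is modelled).  HbR is `hbr_ratio` times the HbO
#' event component.  Noise is added in concentration space: sinusoids at the
#' cardiac (1.1 Hz), respiratory (0.3 Hz) and Mayer-wave (0.1 Hz) frequencies
#' with one random phase per subject and component — systemic physiology is
#' coherent across the probe, so channel averaging does not cancel it — plus
#' an independent linear drift (Gaussian random slope) and white Gaussian
#' noise per channel.
#'
#' @param schedule Output of [generate_schedule()].
#' @param config The same [sim_config()].
#' @return Named list (one element per subject) of `hemo_series` objects:
#'   `list(subject, fs_hz, time_s, hbo, hbr)` with `hbo`/`hbr` sample-by-channel
#'   matrices in umol/L.
#' @export
generate_hemodynamics <- function(schedule, config) {
  stopifnot(inherits(config, "sim_config"))
  t <- sim_time_grid(config)
  kern <- event_kernel(config$fs_hz, config$claim_s)
  noise_seeds <- derive_seeds(config$seed + 1L, config$n_subjects)
  subjects <- sort(unique(schedule$subject))
  out <- lapply(subjects, function(s) {
    rows <- schedule[schedule$subject == s, , drop = FALSE]
    clean <- numeric(length(t))
    for (i in seq_len(nrow(rows))) {
      amp <- if (rows$label[i] == "lie") config$amp_lie_uM else config$amp_truth_uM
      k0 <- floor(rows$claim_onset_s[i] * config$fs_hz)  # first sample at/after onset
      k0 <- k0 + (t[k0 + 1] < rows$claim_onset_s[i] - 1e-9)
      span <- seq_len(min(length(kern), length(t) - k0))
      clean[k0 + span] <- clean[k0 + span] + amp * kern[span]
    }
    hbo <- matrix(clean, nrow = length(t), ncol = config$n_channels)
    hbr <- config$hbr_ratio * hbo
    with_seed(noise_seeds[match(s, subjects)], {
      systemic <- sim_systemic_noise(t, config)
      for (ch in seq_len(config$n_channels)) {
        hbo[, ch] <- hbo[, ch] + systemic + sim_channel_noise(t, config)
        hbr[, ch] <- hbr[, ch] + config$hbr_ratio *
          (systemic + sim_channel_noise(t, config))
      }
    })
    colnames(hbo) <- colnames(hbr) <- channel_names(config$n_channels)
    structure(
      list(subject = s, fs_hz = config$fs_hz, time_s = t, hbo = hbo, hbr = hbr),
      class = "hemo_series"
    )
  })
  names(out) <- paste0("subj", subjects)
  out
}

# Subject-level systemic oscillations, coherent across channels; consumes RNG.
# Each component is a sinusoid at its center frequency with random-walk phase
# noise (heart rate, breathing and vasomotion all wander), so successive
# sessions see decorrelated oscillation phases even though the session length
# is a multiple of every component's nominal period.
sim_systemic_noise <- function(t, config) {
  amps <- c(config$noise_cardiac_uM, config$noise_resp_uM, config$noise_mayer_uM)
  dt <- if (length(t) > 1) t[2] - t[1] else 1
  noise <- numeric(length(t))
  for (j in seq_along(amps)) {
    phi0 <- stats::runif(1, 0, 2 * pi)
    wander <- cumsum(c(0, stats::rnorm(length(t) - 1, 0,
                                       config$noise_phase_sd * sqrt(dt))))
    noise <- noise + amps[j] * sin(2 * pi * .noise_freqs[j] * t + phi0 + wander)
  }
  noise
}

# one channel's independent noise: linear drift + white (umol/L); consumes RNG
sim_channel_noise <- function(t, config) {
  slope <- stats::rnorm(1, 0, config$noise_drift_uM_s)
  slope * t + stats::rnorm(length(t), 0, config$noise_white_uM)
}

#' Project hemoglobin concentrations to raw detected light intensities
#'
#' The forward model inverted by the modified Beer-Lambert conversion: for
#' each channel and wavelength i,
#' `dOD_i(k) = l * dpf_i * (alpha_HbO_i * dHbO(k) + alpha_HbR_i * dHbR(k))`
#' and `I_i(k) = i0 * exp(-dOD_i(k))`, so increased absorption yields reduced
#' detected light.  Output intensities are strictly positive by construction.
#'
#' @param hemo A `hemo_series` (see [generate_hemodynamics()]).
#' @param constants [optical_constants()].
#' @param config [sim_config()] (supplies the baseline intensity `i0`).
#' @return An `intensity_recording`: `list(subject, fs_hz, time_s, intensity)`
#'   with `intensity` a sample-by-column matrix, columns
#'   `ch01_w1, ch01_w2, ..., chNN_w2`.
#' @export
forward_project <- function(hemo, constants, config) {
  stopifnot(inherits(hemo, "hemo_series"), inherits(constants, "optical_constants"))
  if (config$i0 <= 0) stop_cfg("i0 must be positive, got %g", config$i0)
  a <- build_system_matrix(constants)
  nch <- ncol(hemo$hbo)
  inten <- matrix(NA_real_, nrow = nrow(hemo$hbo), ncol = 2 * nch)
  for (ch in seq_len(nch)) {
    od <- cbind(hemo$hbo[, ch], hemo$hbr[, ch]) %*% t(a)  # n x 2, cols = wavelengths
    inten[, 2 * ch - 1] <- config$i0 * exp(-od[, 1])
    inten[, 2 * ch] <- config$i0 * exp(-od[, 2])
  }
  colnames(inten) <- intensity_colnames(nch)
  structure(
    list(subject = hemo$subject, fs_hz = hemo$fs_hz, time_s = hemo$time_s,
         intensity = inten),
    class = "intensity_recording"
  )
}

#' Simulate a complete labeled bluff-game fNIRS dataset
#'
#' Composes [generate_schedule()], [generate_hemodynamics()] and
#' [forward_project()] into a ground-truth dataset: the schedule, the true
#' concentration series and the emitted raw-intensity recordings per subject.
#' Fully deterministic given `config$seed`.
#'
#' @param config [sim_config()].
#' @param constants [optical_constants()] used by the forward model.
#' @param out_dir Optional directory; when given, intensity and events TSV
#'   files are written there (see [write_intensity_tsv()], [write_events_tsv()]).
#' @return Object of class `bluff_dataset`:
#'   `list(config, constants, schedule, hemo, recordings)`.
#' @examples
#' ds <- simulate_experiment(sim_config(n_subjects = 1, n_sessions = 4, seed = 3))
#' nrow(ds$schedule)
#' @export
simulate_experiment <- function(config, constants = optical_constants(),
                                out_dir = NULL) {
  schedule <- generate_schedule(config)
  hemo <- generate_hemodynamics(schedule, config)
  recordings <- lapply(hemo, forward_project, constants = constants,
                       config = config)
  ds <- structure(
    list(config = config, constants = constants, schedule = schedule,
         hemo = hemo, recordings = recordings),
    class = "bluff_dataset"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (rec in recordings) {
      write_intensity_tsv(rec, file.path(out_dir,
        sprintf("subj%02d_intensity.tsv", rec$subject)))
    }
    write_events_tsv(schedule, config, file.path(out_dir, "events.tsv"))
  }
  ds
}
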