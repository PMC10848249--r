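#' Optical-density change from raw detected intensities
#'
#' Computes `dOD(k) = -ln(I(k) / I_ref)` per channel and wavelength, so that a
#' drop in detected light (more absorption, more hemoglobin) gives a positive
#' optical-density change.  The reference `I_ref` is the mean detected
#' intensity over a baseline window, by default the first card-arrangement
#' phase `[0, 15) s`; incident light is unobservable in continuous-wave fNIRS,
#' so a within-recording reference is the operational choice.  Because the
#' reference scales with the data, multiplying all intensities by a constant
#' leaves `dOD` unchanged.
#'
#' @param recording An `intensity_recording` (see [forward_project()] or
#'   [read_intensity_tsv()]).
#' @param baseline_s Two-element numeric, the half-open reference window in
#'   seconds; `NULL` uses the whole recording.
#' @return An `od_series`: `list(subject, fs_hz, time_s, od)` with `od` the
#'   sample-by-column matrix of dimensionless optical-density changes, columns
#'   as in the input.
#' @export
compute_delta_od <- function(recording, baseline_s = c(0, 15)) {
  stopifnot(inherits(recording, "intensity_recording"))
  inten <- recording$intensity
  if (nrow(inten) < 2) stop_cfg("need at least 2 samples, got %d", nrow(inten))
  bad <- which(inten <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop_cfg("non-positive intensity in column '%s' at sample %d",
             colnames(inten)[bad[1, 2]], bad[1, 1])
  }
  if (is.null(baseline_s)) {
    in_base <- rep(TRUE, nrow(inten))
  } else {
    stopifnot(length(baseline_s) == 2, baseline_s[1] < baseline_s[2])
    in_base <- recording$time_s >= baseline_s[1] & recording$time_s < baseline_s[2]
    if (!any(in_base)) stop_cfg("baseline window [%g, %g) contains no samples",
                                baseline_s[1], baseline_s[2])
  }
  i_ref <- colMeans(inten[in_base, , drop = FALSE])
  od <- -log(sweep(inten, 2, i_ref, "/"))
  structure(
    list(subject = recording$subject, fs_hz = recording$fs_hz,
         time_s = recording$time_s, od = od),
    class = "od_series"
  )
}

#' Invert the modified Beer-Lambert law
#'
#' Solves, per channel and sample, the 2x2 linear system
#' `(dOD_l1, dOD_l2) = A (dHbO, dHbR)` for the hemoglobin concentration
#' changes, where `A` is [build_system_matrix()].  The map is linear in the
#' optical densities.
#'
#' @param od An `od_series` from [compute_delta_od()]; columns must be the
#'   `chXX_w1`/`chXX_w2` pairs.
#' @param constants [optical_constants()].
#' @return A `hemo_series` with `hbo` and `hbr` sample-by-channel matrices in
#'   umol/L.
#' @export
od_to_hemoglobin <- function(od, constants) {
  stopifnot(inherits(od, "od_series"))
  a <- build_system_matrix(constants)
  cols <- colnames(od$od)
  w1 <- grep("_w1$", cols)
  w2 <- grep("_w2$", cols)
  if (length(w1) != length(w2) || length(w1) == 0) {
    stop_cfg("expected matched chXX_w1/chXX_w2 column pairs, got %d vs %d",
             length(w1), length(w2))
  }
  if (!identical(sub("_w1$", "", cols[w1]), sub("_w2$", "", cols[w2]))) {
    stop_cfg("wavelength columns are not paired by channel")
  }
  a_inv <- solve(a)
  nch <- length(w1)
  hbo <- matrix(NA_real_, nrow(od$od), nch)
  hbr <- matrix(NA_real_, nrow(od$od), nch)
  for (ch in seq_len(nch)) {
    conc <- cbind(od$od[, w1[ch]], od$od[, w2[ch]]) %*% t(a_inv)
    hbo[, ch] <- conc[, 1]
    hbr[, ch] <- conc[, 2]
  }
  colnames(hbo) <- colnames(hbr) <- sub("_w1$", "", cols[w1])
  structure(
    list(subject = od$subject, fs_hz = od$fs_hz, time_s = od$time_s,
         hbo = hbo, hbr = hbr),
    class = "hemo_series"
  )
}

#' Raw intensities to hemoglobin concentration changes
#'
#' Convenience composition of [compute_delta_od()] and [od_to_hemoglobin()].
#'
#' @inheritParams compute_delta_od
#' @inheritParams od_to_hemoglobin
#' @return A `hemo_series`.
#' @export
convert_recording <- function(recording, constants = optical_constants(),
                              baseline_s = c(0, 15)) {
  od_to_hemoglobin(compute_delta_od(recording, baseline_s), constants)
}
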