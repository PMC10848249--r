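test_that("schedules are seeded-deterministic, contiguous and label-complete", {
  cfg <- sim_config(seed = 7)
  s1 <- generate_schedule(cfg)
  s2 <- generate_schedule(cfg)
  expect_identical(s1, s2)

  one <- s1[s1$subject == 1, ]
  expect_equal(nrow(one), 20)
  expect_equal(one$onset_s, (0:19) * 30)
  expect_equal(one$claim_onset_s, one$onset_s + 15)
  # last session ends at 10 minutes
  expect_equal(one$onset_s[20] + cfg$session_s, 600)
  # the bluff deck forces at least 4 lies per subject
  lies <- tapply(s1$label == "lie", s1$subject, sum)
  expect_true(all(lies >= 4))
})

test_that("min-lie constraint places exactly the minimum when lie_fraction = 0", {
  cfg <- sim_config(lie_fraction = 0, seed = 3)
  sched <- generate_schedule(cfg)
  lies <- tapply(sched$label == "lie", sched$subject, sum)
  expect_true(all(lies == 4))
})

test_that("lie_fraction outside [0,1] is a configuration error", {
  expect_error(sim_config(lie_fraction = 1.2), "lie_fraction")
  expect_error(sim_config(lie_fraction = -0.1), "lie_fraction")
})

test_that("empirical lie fraction matches lie_fraction at large n", {
  cfg <- sim_config(n_subjects = 1, n_sessions = 2000, lie_fraction = 0.35,
                    seed = 5)
  sched <- generate_schedule(cfg)
  phat <- mean(sched$label == "lie")
  half <- 1.96 * sqrt(0.35 * 0.65 / 2000)
  expect_lt(abs(phat - 0.35), half + 1e-12)
})

test_that("silent configuration yields identically zero concentration series", {
  cfg <- quiet_config(amp_lie_uM = 0, amp_truth_uM = 0)
  hemo <- generate_hemodynamics(generate_schedule(cfg), cfg)
  expect_equal(max(abs(hemo[[1]]$hbo)), 0)
  expect_equal(max(abs(hemo[[1]]$hbr)), 0)
})

test_that("a single noise-free lie event reproduces the HRF-boxcar convolution", {
  cfg <- quiet_config(n_sessions = 1, lie_fraction = 1, min_lies = 1,
                      amp_lie_uM = 1)
  sched <- generate_schedule(cfg)
  expect_equal(sched$label, "lie")
  hemo <- generate_hemodynamics(sched, cfg)
  x <- hemo[[1]]$hbo[, 1]

  # independent oracle: direct convolution of the double-gamma HRF with a
  # 5 s boxcar on the same grid, peak-normalized
  fs <- cfg$fs_hz
  tg <- seq(0, 32, by = 1 / fs)
  h <- dgamma(tg, 6, 1) - dgamma(tg, 16, 1) / 6
  box <- rep(1, floor(5 * fs))
  conv <- stats::convolve(c(h, numeric(length(box))), rev(box), type = "open")
  conv <- conv[seq_along(tg)]
  conv <- conv / max(conv)

  expect_equal(max(x), 1, tolerance = 1e-12)
  onset_idx <- which(hemo[[1]]$time_s >= sched$claim_onset_s[1])[1]
  got <- x[onset_idx:length(x)]
  expect_equal(got, conv[seq_along(got)], tolerance = 1e-12)
  # HbR mirrors HbO at the configured ratio
  expect_equal(hemo[[1]]$hbr[, 1], -x / 3, tolerance = 1e-12)
})

test_that("with equal amplitudes the SM feature carries no label information", {
  tab <- extract_features(simulate_experiment(null_config(seed = 8)))
  expect_equal(nrow(tab), 200)
  ks <- suppressWarnings(
    ks.test(tab$sm[tab$label == "lie"], tab$sm[tab$label == "truth"]))
  expect_gt(ks$p.value, 0.01)
})

test_that("forward projection is exact and strictly positive", {
  oc <- optical_constants()
  a <- build_system_matrix(oc)
  cfg <- quiet_config()
  hemo <- generate_hemodynamics(generate_schedule(cfg), cfg)[[1]]
  rec <- forward_project(hemo, oc, cfg)

  expect_true(all(rec$intensity > 0))
  # zero concentration => intensity equals i0 everywhere it is zero
  zero_rows <- which(hemo$hbo[, 1] == 0 & hemo$hbr[, 1] == 0)
  expect_true(length(zero_rows) > 0)
  expect_equal(unname(rec$intensity[zero_rows, 1]),
               rep(cfg$i0, length(zero_rows)))
  # dOD is linear in the path length: doubling l doubles -log(I/i0)
  oc2 <- optical_constants(l_cm = 2 * oc$l_cm)
  rec2 <- forward_project(hemo, oc2, cfg)
  od1 <- -log(rec$intensity / cfg$i0)
  od2 <- -log(rec2$intensity / cfg$i0)
  expect_equal(od2, 2 * od1, tolerance = 1e-9)
})

test_that("simulated dataset has the experiment's dimensions", {
  ds <- simulate_experiment(sim_config(seed = 1))
  expect_equal(nrow(ds$schedule), 200)  # 10 subjects x 20 sessions
  expect_length(ds$recordings, 10)
  expect_equal(ncol(ds$recordings[[1]]$intensity), 24)  # 12 channels x 2 wl
  expect_equal(colnames(ds$recordings[[1]]$intensity)[1:3],
               c("ch01_w1", "ch01_w2", "ch02_w1"))
})

test_that("simulation is byte-identical under one seed and differs across seeds", {
  cfg <- sim_config(n_subjects = 2, n_sessions = 5, seed = 9)
  d1 <- simulate_experiment(cfg)
  d2 <- simulate_experiment(cfg)
  expect_identical(d1$recordings, d2$recordings)
  cfg2 <- sim_config(n_subjects = 2, n_sessions = 5, seed = 10)
  d3 <- simulate_experiment(cfg2)
  expect_false(identical(d1$recordings[[1]]$intensity,
                         d3$recordings[[1]]$intensity))
})

test_that("cardiac-only optical density peaks at 1.1 Hz", {
  cfg <- sim_config(n_subjects = 1, n_sessions = 2, min_lies = 0,
                    amp_lie_uM = 0, amp_truth_uM = 0, noise_resp_uM = 0,
                    noise_mayer_uM = 0, noise_drift_uM_s = 0,
                    noise_white_uM = 0, seed = 42)
  ds <- simulate_experiment(cfg)
  od <- compute_delta_od(ds$recordings[[1]], baseline_s = NULL)
  x <- od$od[, 1]
  n <- length(x)
  sp <- Mod(fft(x - mean(x)))[2:(n %/% 2)]
  freqs <- seq_along(sp) * cfg$fs_hz / n
  bin <- cfg$fs_hz / n
  expect_lt(abs(freqs[which.max(sp)] - 1.1), bin + 1e-12)
})
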