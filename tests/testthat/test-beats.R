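noiseless_sim <- function(n_beats, rr_mean, rr_sd = 0, seed = 1, qr = 8) {
  cfg <- sim_config(n_beats = n_beats, rr_mean_ms = rr_mean, rr_sd_ms = rr_sd,
                    qr_ms = qr, noise_sd = 0, seed = seed)
  simulate_recording(cfg)
}

test_that("detect_r_peaks recovers a clean beat train exactly", {
  sim <- noiseless_sim(9, 256)             # 10 rendered QRS complexes
  r <- detect_r_peaks(sim$signal)
  expect_length(r, 10)
  expect_equal(r[-1], sim$truth$r_time_ms)
  expect_true(all(diff(r) >= 120))
})

test_that("detect_r_peaks handles degenerate signals", {
  flat <- ecg_signal(rep(0, 1000))
  expect_error(detect_r_peaks(flat), "no R peaks")
  # a single beat
  one <- noiseless_sim(1, 256)
  r <- detect_r_peaks(one$signal)
  expect_length(r, 2)
})

test_that("detect_q finds the trough preceding each R", {
  sim <- noiseless_sim(9, 256)
  r <- detect_r_peaks(sim$signal)
  q <- detect_q(sim$signal, r)
  expect_equal(q, r - 8)

  # R at the very start of the signal: beat skipped with a warning
  clipped <- ecg_signal(sim$signal$samples, fs = 1000, t0_ms = 0)
  expect_warning(q2 <- detect_q(clipped, c(0, r)), "skipped")
  expect_true(is.na(q2[1]))
  expect_equal(q2[-1], q)

  # monotone rising ramp into the peak: minimum falls at the window edge
  ramp <- ecg_signal(c(seq(0, 1, length.out = 200), seq(1, 0, length.out = 50)))
  qr <- detect_q(ramp, 199, window_ms = 20)
  expect_equal(qr, 180)
})

test_that("build_beat_table drops the first beat and assembles QT per beat", {
  sim <- noiseless_sim(9, 256)
  bt <- build_beat_table(sim$signal)
  expect_equal(nrow(bt), 9)
  expect_equal(bt$rr_ms, rep(256, 9))
  expect_equal(bt$qt_ms, rep(133, 9), tolerance = 1e-6)
  expect_equal(bt$qt_ms, (bt$r_time_ms - bt$q_time_ms) + bt$t_end_ms)

  # two R peaks give a single record
  one <- noiseless_sim(1, 256)
  expect_equal(nrow(build_beat_table(one$signal)), 1)

  # longer beats: RR 390 regime
  long <- noiseless_sim(20, 390)
  bt390 <- build_beat_table(long$signal)
  expect_equal(mean(bt390$qt_ms), 170, tolerance = 0.5)
})

test_that("beat tables respect interval orderings", {
  sim <- noiseless_sim(30, 300, rr_sd = 40, seed = 4)
  bt <- build_beat_table(sim$signal)
  expect_true(all(bt$q_time_ms < bt$r_time_ms))
  expect_true(all(bt$qt_ms < bt$rr_ms))
  expect_true(all(bt$t_end_ms > 0))
})

test_that("summarize_record reports sample mean and SD", {
  s <- summarize_record(data.frame(rr_ms = c(256, 256, 256),
                                   qt_ms = c(133, 133, 133)))
  expect_equal(s$n, 3)
  expect_equal(s$qt_mean_ms, 133)
  expect_equal(s$qt_sd_ms, 0)

  s2 <- summarize_record(data.frame(rr_ms = c(250, 260), qt_ms = c(132, 134)))
  expect_equal(s2$qt_mean_ms, 133)
  expect_equal(s2$qt_sd_ms, sqrt(2), tolerance = 1e-9)

  expect_error(summarize_record(data.frame()), "empty")
})

test_that("a Fetus-4-like regime yields the expected record summary", {
  sim <- noiseless_sim(48, 276, rr_sd = 1.1, seed = 11)
  s <- summarize_record(build_beat_table(sim$signal))
  expect_equal(s$n, 48)
  expect_equal(s$qt_mean_ms, 139, tolerance = 1)
})

test_that("fiducial detection recovers truth under 20 dB noise", {
  cfg0 <- sim_config(n_beats = 200, rr_mean_ms = 264, rr_sd_ms = 28,
                     noise_sd = 0, seed = 42)
  clean <- simulate_recording(cfg0)
  snr_noise_sd <- sqrt(mean(clean$signal$samples^2)) / 10  # 20 dB below RMS
  cfg <- sim_config(n_beats = 200, rr_mean_ms = 264, rr_sd_ms = 28,
                    noise_sd = snr_noise_sd, seed = 42)
  sim <- simulate_recording(cfg)
  r <- detect_r_peaks(sim$signal)
  expect_length(r, 201)
  q <- detect_q(sim$signal, r)
  r_err <- abs(r[-1] - sim$truth$r_time_ms)
  q_err <- abs(q[-1] - sim$truth$q_time_ms)
  expect_gte(mean(r_err <= 1), 0.99)
  expect_gte(mean(q_err <= 1), 0.99)
})

test_that("qc_report counts beats and flags RR outliers", {
  sim <- noiseless_sim(30, 280, rr_sd = 5, seed = 12)
  bt <- build_beat_table(sim$signal)
  qc <- qc_report(bt)
  expect_equal(qc$n_beats, 30)
  expect_length(qc$flagged, 0)
  # a dropped beat shows up as a doubled RR and gets flagged
  bt$rr_ms[7] <- 2 * bt$rr_ms[7]
  expect_equal(qc_report(bt)$flagged, 7)
})

test_that("detection is deterministic on a fixed signal", {
  sim <- noiseless_sim(10, 280, rr_sd = 10, seed = 3)
  expect_identical(build_beat_table(sim$signal), build_beat_table(sim$signal))
})
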