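test_that("decay_amplitude matches the closed form and rejects bad input", {
  expect_equal(decay_amplitude(0, 256, 100), 100)
  expect_equal(decay_amplitude(256, 256, 100), 100 * exp(-2 * pi))
  expect_equal(decay_amplitude(128, 256, 100), 100 * exp(-pi))
  # vectorized and strictly decreasing
  a <- decay_amplitude(0:255, 256)
  expect_true(all(diff(a) < 0))
  expect_error(decay_amplitude(10, 0), "rr_ms")
  expect_error(decay_amplitude(10, -5), "rr_ms")
  expect_error(decay_amplitude(-1, 256), "t_ms")
})

test_that("sample_decay discretizes one beat on the sampling grid", {
  curve <- sample_decay(256)
  expect_length(curve$times_ms, 256)
  expect_equal(curve$amplitudes[1], 100)
  expect_true(all(diff(curve$amplitudes) < 0))
  expect_true(all(curve$amplitudes > 0 & curve$amplitudes <= 100))

  c390 <- sample_decay(390)
  expect_length(c390$times_ms, 390)
  expect_equal(c390$amplitudes[390], 100 * exp(-2 * pi * 389 / 390))

  # non-integer RR and non-default fs still exclude the endpoint
  c2 <- sample_decay(255.5, model_config(fs = 2000))
  expect_true(max(c2$times_ms) < 255.5)
  expect_equal(diff(c2$times_ms)[1], 0.5)

  expect_error(sample_decay(1.5), "too short")
})

test_that("threshold_k reproduces the closed-form constant for both species", {
  p <- threshold_k(256)
  expect_equal(p$x, 1000 / 256)
  # period mean converges to 100 (1 - e^(-2 pi)) / (2 pi) = 15.886
  expect_lt(abs(p$mean_amp - oracle_period_mean()), 0.1)
  expect_equal(p$k, oracle_k(256), tolerance = 1e-3)
  expect_equal(p$k, 4.479, tolerance = 1e-3)
  expect_equal(p$band_low, p$k - 0.5)
  expect_equal(p$band_high, p$k + 1)

  expect_equal(threshold_k(390)$k, 7.151, tolerance = 1e-3)

  h <- threshold_k(256, model_config(species = "human"))
  expect_equal(h$k, oracle_k(256, "human"), tolerance = 1e-3)
  expect_equal(h$k, 2.832, tolerance = 1e-3)
  # smaller threshold band sits later on the decay -> longer T end in humans
  expect_lt(h$k, p$k)
})

test_that("t_end is the median of the in-band sample times", {
  cfg <- model_config()
  te256 <- t_end(sample_decay(256, cfg), threshold_k(256, cfg))
  expect_equal(te256, oracle_t_end(256), tolerance = 1)  # oracle: 124.85
  te390 <- t_end(sample_decay(390, cfg), threshold_k(390, cfg))
  expect_equal(te390, oracle_t_end(390), tolerance = 1)  # oracle: 161.92
  expect_gt(te256, 0)
  expect_lt(te256, 256)

  # band pushed entirely below the smallest sampled amplitude -> empty set
  params <- threshold_k(256, cfg)
  params$band_low <- 0.01
  params$band_high <- 0.05
  expect_error(t_end(sample_decay(256, cfg), params), "band")
})

test_that("even-sized band sets take the mean of the two central times", {
  cfg <- model_config()
  curve <- sample_decay(256, cfg)
  params <- threshold_k(256, cfg)
  # widen the band by one sample if needed to force an even count
  sel <- which(curve$amplitudes > params$band_low &
                 curve$amplitudes < params$band_high)
  if (length(sel) %% 2 == 1) {
    params$band_high <- curve$amplitudes[min(sel) - 1] + 1e-9
    sel <- c(min(sel) - 1, sel)
  }
  expect_equal(t_end(curve, params),
               mean(curve$times_ms[sel[length(sel) / 2 + c(0, 1)]]))
})

test_that("qt_from_rr assembles QT with the Q-R offset", {
  est <- qt_from_rr(c(256, 390))
  expect_equal(est$qt_ms[1], 133, tolerance = 0.01)
  expect_equal(est$qt_ms[2], 170, tolerance = 0.01)
  expect_equal(est$qt_ms, est$t_end_ms + 8)
  # zero offset: QT equals the T end
  z <- qt_from_rr(256, model_config(qr_offset_ms = 0))
  expect_equal(z$qt_ms, z$t_end_ms)
})

test_that("discrete T end tracks the continuous oracle within 1 ms and is monotone", {
  cfg <- model_config()
  rr_grid <- seq(200, 450, by = 10)
  te <- vapply(rr_grid, function(rr)
    t_end(sample_decay(rr, cfg), threshold_k(rr, cfg)), numeric(1))
  expect_true(all(abs(te - vapply(rr_grid, oracle_t_end, numeric(1))) <= 1))
  expect_true(all(diff(te) > 0))
})

test_that("the threshold band is non-empty across the physiological RR range", {
  cfg <- model_config()
  for (rr in seq(150, 600, by = 25)) {
    te <- t_end(sample_decay(rr, cfg), threshold_k(rr, cfg))
    expect_true(te > 0 && te < rr)
  }
})

test_that("the model path is deterministic", {
  a <- qt_from_rr(c(256, 333.7, 390))
  b <- qt_from_rr(c(256, 333.7, 390))
  expect_identical(a, b)
})

test_that("model_config validates its fields", {
  expect_error(model_config(v0 = 0), "v0")
  expect_error(model_config(fs = -1), "fs")
  expect_error(model_config(species = "rat"))
  expect_error(model_config(qr_offset_ms = -2), "qr_offset_ms")
  expect_equal(model_config(species = "human")$species, "human")
})
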