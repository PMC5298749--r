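test_that("QRS detector marks nothing on a flat line", {
  flat <- waveform(rep(1, 2000), fs = 250)
  ann <- detect_qrs(flat)
  expect_length(ann$r_indices, 0)
})

test_that("QRS detector recovers generator ground truth at zero noise", {
  e <- gen_ecg(60, duration_s = 10, fs = 250, noise_sd = 0, seed = 1)
  ann <- detect_qrs(e$waveform)
  expect_length(ann$r_indices, length(e$truth$event_indices))
  expect_true(all(abs(ann$r_indices - e$truth$event_indices) <= 2))
})

test_that("refractory period suppresses a second nearby complex", {
  # two identical spikes 40 samples apart with a 50-sample refractory
  s <- numeric(600)
  s[c(100, 140)] <- 1
  ann <- detect_qrs(waveform(s, fs = 250),
                    detector_config(buffer_n = 600, refractory = 50))
  expect_length(ann$r_indices, 1)
  # with the refractory shorter than the gap both are kept
  ann2 <- detect_qrs(waveform(s, fs = 250),
                     detector_config(buffer_n = 600, refractory = 20))
  expect_length(ann2$r_indices, 2)
})

test_that("no two reported ridges are closer than the refractory", {
  for (seed in 1:5) {
    e <- gen_ecg(sample(80:180, 1), duration_s = 12, noise_sd = 0.05,
                 jitter_frac = 0.15, seed = seed)
    cfg <- detector_config()
    ann <- detect_qrs(e$waveform, cfg)
    if (length(ann$r_indices) > 1)
      expect_true(all(diff(ann$r_indices) > cfg$refractory))
  }
})

test_that("detector rejects signals shorter than one buffer", {
  expect_error(detect_qrs(waveform(rnorm(500), fs = 250)), "buffer")
})

test_that("heart rate follows the averaged-RR equation", {
  ann <- structure(list(r_indices = c(1L, 251L, 501L, 751L), fs = 250),
                   class = "qrs_annotation")
  est <- heart_rate(ann)
  expect_equal(est$hr_bpm, 60)          # RR = Fs -> 60 bpm
  expect_equal(est$rr_avg_interval, 250)

  ann2 <- structure(list(r_indices = c(1L, 201L, 401L, 601L), fs = 250),
                    class = "qrs_annotation")
  expect_equal(heart_rate(ann2)$hr_bpm, 75)   # 60 * 250 / 200

  single <- structure(list(r_indices = 10L, fs = 250),
                      class = "qrs_annotation")
  expect_error(heart_rate(single), "two R ridges")
})

test_that("rate-equation identity holds exactly for any annotation", {
  for (seed in 1:10) {
    set.seed(seed)
    idx <- cumsum(c(1L, sample(60:400, 20, replace = TRUE)))
    ann <- structure(list(r_indices = idx, fs = 250),
                     class = "qrs_annotation")
    est <- heart_rate(ann)
    expect_identical(est$hr_bpm, 60 * 250 / est$rr_avg_interval)
    expect_equal(est$hr_bpm * est$rr_avg_interval, 60 * 250,
                 tolerance = 1e-12)
  }
})

test_that("heart-rate recovery tolerates 5% amplitude noise", {
  errs <- vapply(c(50, 90, 140, 170), function(hr) {
    e <- gen_ecg(hr, duration_s = 20, noise_sd = 0.05, seed = hr)
    abs(heart_rate(detect_qrs(e$waveform))$hr_bpm - hr)
  }, numeric(1))
  expect_true(all(errs <= 3))
})

test_that("respiration rate is read off threshold crossings", {
  # pure 0.25 Hz sinusoid -> 15 breaths/min
  t <- seq(0, 60 - 1 / 25, by = 1 / 25)
  w <- waveform(sin(2 * pi * 0.25 * t), fs = 25)
  expect_equal(respiration_rate(w), 15, tolerance = 1e-6)

  r <- gen_respiration(12, duration_s = 60, noise_sd = 0, seed = 1)
  expect_equal(respiration_rate(r$waveform), 12, tolerance = 0.5)

  expect_error(respiration_rate(waveform(rep(2, 100), fs = 25)),
               "constant")
})

test_that("SpO2 calibration maps the ratio of ratios as declared", {
  # R = 0.4 under the default line: 110 - 25 * 0.4 = 100 (clamped top)
  t <- seq(0, 10, by = 0.01)
  pulse <- sin(2 * pi * 1.2 * t)
  mk <- function(dc, perf) waveform(dc * (1 + perf / 2 * pulse), fs = 100)
  ppg <- dual_ppg(red = mk(1, 0.4 * 0.05), ir = mk(1, 0.05))
  expect_equal(estimate_spo2(ppg), 100)
  expect_equal(estimate_spo2(gen_ppg(92, seed = 1)$ppg), 92,
               tolerance = 0.5)
  # zero red DC is an error, not a clamp
  dead <- dual_ppg(red = waveform(rep(0, length(t)), fs = 100),
                   ir = mk(1, 0.05))
  expect_error(estimate_spo2(dead), "DC")
})

test_that("SpO2 decreases strictly as the ratio of ratios grows", {
  spo2 <- vapply(seq(70, 100, by = 5), function(s)
    estimate_spo2(gen_ppg(s, seed = 1)$ppg), numeric(1))
  expect_true(all(diff(spo2) > 0))  # generator R decreases with SpO2
})

test_that("bridge temperature inverts the generator exactly", {
  for (tc in c(-5, 0, 25, 36.6, 37, 41.3, 60))
    expect_equal(body_temperature(gen_rtd_voltage(tc)), tc,
                 tolerance = 0.01)
  expect_error(body_temperature(10, bridge_config()), "range")
})

test_that("GSR divider arithmetic matches the declared relation", {
  full <- 2^10 - 1
  expect_equal(gsr_resistance(full / 2, 10, 3.3, 1e5), 1e5)  # equal arms
  expect_equal(gsr_resistance(0, 10, 3.3, 1e5), 0)
  expect_error(gsr_resistance(full, 10, 3.3, 1e5), "open circuit")
})

test_that("fall detector fires only on the fall scenario", {
  expect_identical(nrow(detect_fall(gen_accel("stand", seed = 1))), 0L)
  expect_identical(nrow(detect_fall(gen_accel("walk", seed = 1))), 0L)
  expect_identical(nrow(detect_fall(gen_accel("lie", seed = 1))), 0L)
  ev <- detect_fall(gen_accel("fall", seed = 1))
  expect_identical(nrow(ev), 1L)
  expect_gte(ev$impact_g, 2.5)
  expect_gte(ev$freefall_duration_s, 0.06)
})

test_that("a slow deliberate lie-down produces no fall event", {
  # vertical-to-horizontal transition without free fall or impact
  fs <- 50
  t <- seq(0, 8 - 1 / fs, by = 1 / fs)
  frac <- pmin(1, pmax(0, (t - 2) / 3))     # 3-second controlled roll
  tr <- accel_trace(x = sin(frac * pi / 2), y = numeric(length(t)),
                    z = cos(frac * pi / 2), fs = fs)
  expect_identical(nrow(detect_fall(tr)), 0L)
})

test_that("fall detection is robust across generator seeds", {
  hits <- vapply(1:8, function(s)
    nrow(detect_fall(gen_accel("fall", seed = s))), integer(1))
  expect_true(all(hits == 1L))
  quiet <- vapply(1:8, function(s)
    nrow(detect_fall(gen_accel("walk", seed = s))), integer(1))
  expect_true(all(quiet == 0L))
})
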