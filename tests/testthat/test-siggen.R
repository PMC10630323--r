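test_that("non-physiological configurations are rejected", {
  expect_error(sim_config(hr = 20), "hr")
  expect_error(sim_config(hr = 250), "hr")
  expect_error(sim_config(rr = 2), "rr")
  expect_error(sim_config(spo2 = 60), "spo2")
})

test_that("ECG beat grid follows the configured heart rate exactly", {
  cfg <- sim_config(hr = 60, fs = 125, duration = 10, noise_sd = 0,
                    rsa_frac = 0)
  e <- gen_ecg(cfg)
  expect_gte(length(e$r_peaks), 9)
  expect_lte(length(e$r_peaks), 11)
  expect_true(all(diff(e$r_peaks) == 125))
})

test_that("generation is bit-reproducible under a fixed seed", {
  cfg <- sim_config(duration = 12, seed = 7)
  e1 <- gen_ecg(cfg)
  e2 <- gen_ecg(cfg)
  expect_identical(unclass(e1$signal), unclass(e2$signal))
  expect_identical(e1$r_peaks, e2$r_peaks)
  p1 <- gen_ppg(cfg, e1$r_peaks)
  p2 <- gen_ppg(cfg, e2$r_peaks)
  expect_identical(unclass(p1$signal), unclass(p2$signal))
})

test_that("spectral comb spacing of the ECG equals the beat frequency", {
  cfg <- sim_config(hr = 90, duration = 40, noise_sd = 0.01, seed = 6)
  v <- channel(gen_ecg(cfg)$signal, 1)
  n <- length(v)
  sp <- Mod(stats::fft(v - mean(v)))[seq_len(n %/% 2)]
  freq <- (seq_len(n %/% 2) - 1) * cfg$fs / n
  # the waveform is a harmonic comb at multiples of the cycle-repetition
  # frequency: the spacing of the strongest lines is that frequency
  top <- sort(freq[order(sp, decreasing = TRUE)[1:5]])
  bin <- cfg$fs / n
  expect_lt(abs(stats::median(diff(top)) - 1.5), bin + 1e-9)
})

test_that("PPG pulse peaks lag R-peaks by the configured transit time", {
  cfg <- sim_config(duration = 15, ptt_lag = 200, fs = 125, noise_sd = 0,
                    seed = 2)
  e <- gen_ecg(cfg)
  p <- gen_ppg(cfg, e$r_peaks)
  common <- seq_len(length(p$pulse_peaks))
  expect_true(all(p$pulse_peaks - e$r_peaks[common] == 25))
  expect_error(gen_ppg(cfg, integer(0)), "R-peaks")
})

test_that("stationary configuration yields identical cycle maxima", {
  cfg <- sim_config(duration = 20, hr = 60, noise_sd = 0, drift_amp = 0,
                    rsa_frac = 0, am_frac = 0, seed = 3)
  p <- gen_ppg(cfg, gen_ecg(cfg)$r_peaks)
  g <- channel(p$signal, "green")
  maxima <- vapply(p$pulse_peaks[2:(length(p$pulse_peaks) - 1)],
                   function(i) max(g[(i - 10):(i + 10)]), numeric(1))
  expect_lt(max(maxima) - min(maxima), 1e-9)
})

test_that("channel AC/DC ratios encode SpO2 monotonically", {
  ror <- function(spo2) {
    cfg <- sim_config(duration = 20, spo2 = spo2, drift_amp = 0,
                      noise_sd = 0, seed = 2)
    s <- gen_ppg(cfg, gen_ecg(cfg)$r_peaks)$signal
    acdc <- function(ch) (max(s[, ch]) - min(s[, ch])) / mean(s[, ch])
    acdc("red") / acdc("green")
  }
  r95 <- ror(95)
  r85 <- ror(85)
  expect_gt(r85, r95)
  # the generator's affine convention is recoverable from the waveforms
  expect_lt(abs(spo2_from_ratio(r95) - 95), 1.5)
  expect_lt(abs(spo2_from_ratio(r85) - 85), 1.5)
})

test_that("label streams are consistent with the generating parameters", {
  for (hr in c(55, 95)) {
    cfg <- sim_config(duration = 60, hr = hr, rr = 14, seed = 5)
    rec <- gen_paired_recording(cfg)
    hr_truth <- 60 * cfg$fs / median(diff(rec$r_peaks))
    expect_lt(abs(hr_truth - hr), 2)
    expect_lt(max(abs(rec$labels$hr - hr)), 3)
    # respiratory drift oscillates at the configured rate: count via the
    # dominant low-frequency line of the green channel
    g <- channel(rec$ppg, "green")
    n <- length(g)
    sp <- Mod(stats::fft(g - mean(g)))
    freq <- (seq_len(n) - 1) * cfg$fs / n
    band <- freq > 0.05 & freq < 0.7
    f_resp <- freq[band][which.max(sp[band])]
    expect_lt(abs(f_resp * 60 - cfg$rr), 1)
  }
})

test_that("frame rendering is exact for noise-free constant input", {
  s <- ppg_signal(matrix(117.4, 20, 1), fs = 10)
  fr <- gen_frames(s, height = 8, width = 8, spatial_sd = 0)
  expect_true(all(fr$frames == round(117.4)))
  expect_equal(n_frames(fr), 20)
})

test_that("a 30 s recording at 30 fps yields 900 frames", {
  cfg <- sim_config(fs = 30, duration = 30, seed = 9)
  p <- gen_ppg(cfg, gen_ecg(cfg)$r_peaks)
  fr <- gen_frames(p$signal, height = 12, width = 12, spatial_sd = 1)
  expect_equal(n_frames(fr), 900)
})

test_that("ROI averaging recovers the PPG within the quantization bound", {
  cfg <- sim_config(fs = 30, duration = 10, seed = 8)
  p <- gen_ppg(cfg, gen_ecg(cfg)$r_peaks)
  sd_px <- 3
  h <- 24
  fr <- gen_frames(p$signal, height = h, width = h, spatial_sd = sd_px,
                   seed = 5)
  rec <- extract_ppg(fr, roi(center_fraction = 1))
  err <- max(abs(unclass(rec) - unclass(p$signal)))
  expect_lt(err, 0.5 + 3 * sd_px / sqrt(h * h))
  # correlation of the pulsatile trace survives heavy pixel noise
  fr5 <- gen_frames(p$signal, height = h, width = h, spatial_sd = 5, seed = 6)
  rec5 <- extract_ppg(fr5, roi(center_fraction = 1))
  expect_gt(cor(channel(rec5, "green"), channel(p$signal, "green")), 0.99)
})

test_that("out-of-range intensities clamp with a warning", {
  s <- ppg_signal(matrix(300, 5, 1), fs = 5)
  expect_warning(fr <- gen_frames(s, 4, 4, spatial_sd = 0), "clamp")
  expect_true(all(fr$frames == 255))
})

test_that("caption corpus records are reproducible and round-trip", {
  c1 <- gen_caption_corpus(10, fs = 25, w_s = 4, seed = 12)
  c2 <- gen_caption_corpus(10, fs = 25, w_s = 4, seed = 12)
  expect_identical(c1, c2)
  expect_length(c1, 10)
  for (r in c1) {
    parsed <- parse_caption(r$caption)
    expect_equal(parsed$hr, r$labels$hr)
    expect_equal(parsed$spo2, r$labels$spo2)
    expect_equal(parsed$rr, r$labels$rr)
  }
})

test_that("blood-pressure caption fields are ignored by a vitals parser", {
  cc <- gen_caption_corpus(20, fs = 25, w_s = 4, include_bp = TRUE, seed = 13)
  has_bp <- vapply(cc, function(r) !is.null(r$labels$sbp), logical(1))
  expect_true(any(has_bp))
  r <- cc[[which(has_bp)[1]]]
  parsed <- parse_caption(r$caption, fields = c("hr", "spo2", "rr"))
  expect_named(parsed, c("hr", "spo2", "rr"))
  expect_equal(parse_caption(r$caption, fields = "sbp")$sbp, r$labels$sbp)
})
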