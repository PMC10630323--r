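test_that("flat and constant signals yield no peaks", {
  x <- ppg_signal(rep(0, 1000), fs = 125)
  expect_equal(nrow(terma_detect(x)), 0)
  x2 <- ppg_signal(rep(3.2, 1000), fs = 125)
  expect_equal(nrow(terma_detect(x2)), 0)
})

test_that("R-peak sensitivity exceeds 95% within 40 ms without duplicates", {
  rec <- fixture_recording()
  pk <- terma_detect(rec$ecg, terma_profile_ecg())
  tol <- round(0.04 * 125)
  matched <- vapply(rec$r_peaks,
                    function(r) sum(abs(pk$index - r) <= tol), numeric(1))
  expect_gte(mean(matched >= 1), 0.95)
  expect_true(all(matched <= 1)) # no duplicate detections per beat
})

test_that("ties at a block maximum resolve to the earliest sample", {
  # two identical adjacent samples at the top of an isolated bump
  v <- rep(0, 600)
  v[300:301] <- 5
  v[298:299] <- c(2, 4)
  v[302:303] <- c(4, 2)
  x <- ppg_signal(v, fs = 125)
  pk <- terma_detect(x, terma_profile(event_window = 40, cycle_window = 400))
  expect_equal(nrow(pk), 1)
  expect_equal(pk$index, 300L)
})

test_that("detection is invariant to positive affine transforms", {
  rec <- fixture_recording()
  x <- ppg_signal(channel(rec$ppg, "green"), fs = 125)
  p1 <- terma_detect(x, terma_profile_ppg())
  x2 <- ppg_signal(7.3 * channel(x, 1) + 120, fs = 125)
  p2 <- terma_detect(x2, terma_profile_ppg())
  expect_identical(p1$index, p2$index)
})

test_that("detected heart rate tracks truth across the physiological range", {
  for (hr in c(50, 75, 120, 160)) {
    cfg <- sim_config(duration = 30, hr = hr, seed = 5, noise_sd = 0.02)
    e <- gen_ecg(cfg)
    pk <- terma_detect(e$signal, terma_profile_ecg())
    expect_lt(abs(hr_from_peaks(pk, cfg$fs) - hr), 2)
  }
})

test_that("valleys fall between peaks at the true minima", {
  fs <- 100
  t <- seq(0, 6 - 1 / fs, by = 1 / fs)
  x <- ppg_signal(sin(2 * pi * t), fs = fs)
  peaks <- which(diff(sign(diff(channel(x, 1)))) < 0) + 1
  vl <- detect_valleys(x, peaks)
  expect_equal(nrow(vl), length(peaks) - 1)
  true_minima <- which(diff(sign(diff(channel(x, 1)))) > 0) + 1
  for (v in vl$index) expect_lte(min(abs(true_minima - v)), 1)
  # ordering: every valley value below its neighbouring peaks
  g <- channel(x, 1)
  for (i in seq_len(nrow(vl))) {
    expect_lte(g[vl$index[i]], g[peaks[i]])
    expect_lte(g[vl$index[i]], g[peaks[i + 1]])
  }
  expect_error(detect_valleys(x, peaks[1]), "at least 2")
})

test_that("PQRST fiducials land within 10 ms of the generator truth", {
  cfg <- sim_config(duration = 20, hr = 70, noise_sd = 0, rsa_frac = 0,
                    seed = 6)
  e <- gen_ecg(cfg)
  v <- channel(e$signal, 1)
  fs <- cfg$fs
  r <- e$r_peaks[5]
  period <- diff(e$r_peaks)[5]
  a <- r - round(0.4 * period)
  b <- r + round(0.55 * period)
  cyc <- v[a:b]
  f <- locate_pqrst(cyc, r - a + 1, fs)
  # generator truth: bump centres at the morphology angles
  morph <- ppgvitals:::ecg_morphology_default()
  truth_idx <- (r - a + 1) + round(morph$theta / (2 * pi) * period)
  for (nm in c("P", "Q", "R", "S", "T")) {
    det <- f$index[f$fiducial == nm]
    expect_length(det, 1)
    expect_lte(abs(det - truth_idx[[nm]]), round(0.010 * fs) + 1)
  }
  # amplitude ordering of the default morphology
  amp <- stats::setNames(f$amplitude, f$fiducial)
  expect_true(amp[["R"]] > amp[["P"]])
  expect_gte(amp[["P"]], amp[["T"]] - 1e-12)
  expect_gt(amp[["T"]], 0)
  expect_lt(amp[["S"]], 0)
  expect_lt(amp[["Q"]], 0)
})

test_that("fiducials whose window leaves the cycle are marked absent", {
  cfg <- sim_config(duration = 20, hr = 70, noise_sd = 0, rsa_frac = 0,
                    seed = 6)
  e <- gen_ecg(cfg)
  v <- channel(e$signal, 1)
  r <- e$r_peaks[5]
  a <- r - 40
  cyc <- v[a:(r + 15)] # S fits (80 ms) but the T window (400 ms) does not
  f <- locate_pqrst(cyc, r - a + 1, cfg$fs)
  expect_false("T" %in% f$fiducial)
  expect_true(all(c("Q", "R", "S") %in% f$fiducial))
})

test_that("peak sets validate ordering and serialize as CSV", {
  expect_error(peak_set(c(10, 5)), "increasing")
  p <- peak_set(c(5, 10, 40), kind = "peak")
  path <- tempfile(fileext = ".csv")
  write_peaks(p, path)
  expect_equal(read_peaks(path)$index, p$index)
})
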