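test_that("a pure sinusoid detrends to +/- 0.5 at its extrema", {
  fs <- 100
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  x <- ppg_signal(3 + 2 * sin(2 * pi * t), fs = fs)
  peaks <- which(diff(sign(diff(channel(x, 1)))) < 0) + 1
  valleys <- which(diff(sign(diff(channel(x, 1)))) > 0) + 1
  d <- detrend_envelope(x, peaks, valleys)
  expect_lt(max(abs(channel(d, 1)[peaks] - 0.5)), 1e-6)
  expect_lt(max(abs(channel(d, 1)[valleys] + 0.5)), 1e-6)
})

test_that("linear drift is removed and output magnitude stays in range", {
  cfg <- sim_config(duration = 30, hr = 72, noise_sd = 0, drift_amp = 0,
                    rsa_frac = 0, seed = 3)
  p <- gen_ppg(cfg, gen_ecg(cfg)$r_peaks)
  n <- n_samples(p$signal)
  x <- ppg_signal(channel(p$signal, "green") + 0.01 * seq_len(n), fs = 125)
  pk <- terma_detect(x, terma_profile_ppg())
  vl <- detect_valleys(x, pk)
  d <- detrend_envelope(x, pk, vl)
  inner <- pk$index[1]:pk$index[nrow(pk)]
  y <- channel(d, 1)[inner]
  slope <- stats::coef(stats::lm(y ~ inner))[[2]]
  expect_lt(abs(slope), 1e-4)
  # magnitude between 0 and 1 before the 0.5 offset, i.e. |y| <= 0.5 + eps
  expect_lt(max(abs(y)), 0.5 + 0.05)
})

test_that("detrending is invariant to affine rescaling of the input", {
  rec <- fixture_recording()
  x <- wavelet_filter(ppg_signal(channel(rec$ppg, "green"), fs = 125))
  pk <- terma_detect(x, terma_profile_ppg())
  vl <- detect_valleys(x, pk)
  d1 <- suppressWarnings(detrend_envelope(x, pk, vl))
  x2 <- ppg_signal(3.7 * channel(x, 1) + 11, fs = 125)
  d2 <- suppressWarnings(detrend_envelope(x2, pk, vl))
  expect_lt(max(abs(channel(d1, 1) - channel(d2, 1))), 1e-6)
})

test_that("degenerate envelopes fail with the offending index", {
  x <- ppg_signal(rep(1, 100), fs = 10)
  expect_error(detrend_envelope(x, c(10, 50, 90), c(20, 60, 95)),
               "sample [0-9]+")
  expect_error(detrend_envelope(x, c(10), c(20, 60)), "at least 2")
})

test_that("sliding windows follow the 1 s stride count formula", {
  fs <- 20
  mk <- function(T_sec) {
    ppg_signal(matrix(rnorm(T_sec * fs), ncol = 1), fs = fs)
  }
  labels <- function(T_sec) data.frame(hr = rep(70, T_sec))
  # T = w_s: exactly one window
  ds <- segment_signal(mk(10), labels(10), w_s = 10)
  expect_equal(dim(ds$segments)[1], 1)
  # T = 300, w_s = 20: 281 windows
  ds <- segment_signal(mk(300), labels(300), w_s = 20)
  expect_equal(dim(ds$segments)[1], 281)
  # cross-check by explicit enumeration
  starts <- 0:(300 - 20)
  expect_equal(dim(ds$segments)[1], length(starts))
  expect_error(segment_signal(mk(5), labels(5), w_s = 10), "exceeds")
  expect_error(segment_signal(mk(10), labels(10), w_s = 2.0001),
               "integral")
})

test_that("window labels are window means of the per-second stream", {
  fs <- 10
  T_sec <- 30
  x <- ppg_signal(matrix(rnorm(T_sec * fs), ncol = 1), fs = fs)
  lab <- data.frame(hr = seq_len(T_sec))
  ds <- segment_signal(x, lab, w_s = 10)
  expect_equal(unname(ds$labels[1, "hr"]), mean(1:10))
  expect_equal(unname(ds$labels[5, "hr"]), mean(5:14))
  # constant stream maps every window to the constant
  ds2 <- segment_signal(x, data.frame(hr = rep(63, T_sec)), w_s = 7)
  expect_true(all(ds2$labels == 63))
})

test_that("segment labels preserve the label mass at unit stride", {
  fs <- 5
  T_sec <- 40
  x <- ppg_signal(matrix(0, T_sec * fs, 1), fs = fs)
  lab <- data.frame(hr = runif(T_sec, 60, 100))
  ds <- segment_signal(x, lab, w_s = 4)
  # the mean of window means equals the mean of the covered stream up to
  # edge weighting; compare against the exact enumeration
  expected <- mean(vapply(0:(T_sec - 4),
                          function(s) mean(lab$hr[(s + 1):(s + 4)]),
                          numeric(1)))
  expect_equal(mean(ds$labels), expected)
})

test_that("segment windows carry the right samples and subjects combine", {
  fs <- 4
  x1 <- ppg_signal(matrix(seq_len(40), ncol = 1), fs = fs)
  ds1 <- segment_signal(x1, data.frame(hr = rep(1, 10)), w_s = 2,
                        subject = "a")
  expect_equal(ds1$segments[1, , 1], 1:8)
  expect_equal(ds1$segments[2, , 1], 5:12)
  ds2 <- segment_signal(x1, data.frame(hr = rep(2, 10)), w_s = 2,
                        subject = "b")
  both <- combine_segments(list(ds1, ds2))
  expect_equal(dim(both$segments)[1], 18)
  expect_setequal(unique(both$subject), c("a", "b"))
})
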