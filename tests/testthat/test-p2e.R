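test_that("the pulse-transit lag is recovered exactly without noise", {
  cfg <- sim_config(duration = 30, hr = 60, ptt_lag = 200, fs = 125,
                    noise_sd = 0, drift_amp = 0, rsa_frac = 0, am_frac = 0,
                    seed = 2)
  rec <- gen_paired_recording(cfg)
  ppg <- ppg_signal(channel(rec$ppg, "green"), fs = 125)
  pairs <- pair_cycles(ppg, rec$ecg, rec$pulse_peaks, rec$r_peaks)
  expect_equal(attr(pairs, "lag"), 25)
  # about one cycle pair per beat, a few lost at the recording edges
  expect_gte(length(pairs), length(rec$r_peaks) - 4)
  expect_lte(length(pairs), length(rec$r_peaks) - 1)
  # strictly periodic input: resampled cycles identical across beats
  mat <- t(vapply(pairs, `[[`, numeric(300), "ppg"))
  mid <- 2:(nrow(mat) - 1)
  expect_lt(max(abs(sweep(mat[mid, ], 2, mat[2, ]))), 1e-6)
})

test_that("unmatched peaks beyond tolerance are reported", {
  cfg <- sim_config(duration = 20, hr = 60, fs = 125, noise_sd = 0, seed = 2)
  rec <- gen_paired_recording(cfg)
  ppg <- ppg_signal(channel(rec$ppg, "green"), fs = 125)
  # remove most pulse peaks so matching fails
  expect_error(
    pair_cycles(ppg, rec$ecg, rec$pulse_peaks[c(1, 10)], rec$r_peaks),
    "no matching pulse peak"
  )
})

test_that("truncated DCT inverts exactly at full length and on constants", {
  set.seed(3)
  x <- rnorm(300)
  expect_lt(max(abs(idct_reconstruct(dct_truncate(x, 300), 300) - x)), 1e-9)
  cvec <- rep(2.5, 120)
  co <- dct_truncate(cvec, 120)
  expect_lt(max(abs(co[-1])), 1e-9)
  expect_lt(max(abs(idct_reconstruct(dct_truncate(cvec, 1), 120) - 2.5)),
            1e-9)
  expect_error(dct_truncate(x, 0), "out of range")
  expect_error(dct_truncate(x, 301), "out of range")
})

test_that("half the coefficients reconstruct a smooth ECG cycle within 2%", {
  cfg <- sim_config(duration = 20, hr = 70, noise_sd = 0, rsa_frac = 0,
                    seed = 4)
  rec <- gen_paired_recording(cfg)
  ppg <- ppg_signal(channel(rec$ppg, "green"), fs = 125)
  pairs <- pair_cycles(ppg, rec$ecg, rec$pulse_peaks, rec$r_peaks, L = 300)
  cyc <- pairs[[3]]$ecg
  rec150 <- idct_reconstruct(dct_truncate(cyc, 150), 300)
  rel <- sqrt(sum((cyc - rec150)^2) / sum(cyc^2))
  expect_lt(rel, 0.02)
  # truncation error is non-increasing in the number of kept coefficients
  errs <- vapply(c(25, 75, 150, 300), function(k) {
    sqrt(sum((cyc - idct_reconstruct(dct_truncate(cyc, k), 300))^2))
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-9))
})

test_that("ridge solution matches the normal-equations oracle", {
  set.seed(5)
  n <- 60; lp <- 8; le <- 6; L <- 40
  P <- matrix(rnorm(n * lp), n, lp)
  E <- matrix(rnorm(n * le), n, le)
  pairs <- pairs_from_matrices(P, E, L)
  spec <- p2e_spec("ridge", l_p = lp, l_e = le, lambda = 0.5)
  m <- fit_p2e(pairs, spec)
  Xc <- sweep(P, 2, colMeans(P))
  Yc <- sweep(E, 2, colMeans(E))
  W_oracle <- solve(crossprod(Xc) + 0.5 * diag(lp), crossprod(Xc, Yc))
  expect_lt(max(abs(m$W - W_oracle)), 1e-8)
})

test_that("a planted linear map is recovered to 5% relative error", {
  set.seed(6)
  n <- 2000; p <- 20; L <- 40
  W <- matrix(rnorm(p * p), p, p)
  P <- matrix(rnorm(n * p), n, p)
  E <- P %*% W + 0.01 * matrix(rnorm(n * p), n, p)
  m <- fit_p2e(pairs_from_matrices(P, E, L),
               p2e_spec("ridge", l_p = p, l_e = p, lambda = 1e-3))
  rel <- norm(m$W - W, "F") / norm(W, "F")
  expect_lt(rel, 0.05)
})

test_that("extreme penalties shrink the map to zero", {
  set.seed(7)
  n <- 100; p <- 6; L <- 30
  P <- matrix(rnorm(n * p), n, p)
  E <- P %*% diag(p) + 0.05 * matrix(rnorm(n * p), n, p)
  pairs <- pairs_from_matrices(P, E, L)
  W0 <- fit_p2e(pairs, p2e_spec("ridge", l_p = p, l_e = p, lambda = 0))$W
  W9 <- fit_p2e(pairs, p2e_spec("ridge", l_p = p, l_e = p, lambda = 1e9))$W
  expect_lt(norm(W9, "F"), 1e-3 * norm(W0, "F"))
})

test_that("the closed form agrees with an iterative least-squares fit", {
  set.seed(8)
  n <- 50; p <- 5; L <- 20
  P <- matrix(rnorm(n * p), n, p)
  W_true <- matrix(rnorm(p * p), p, p)
  E <- P %*% W_true + 0.02 * matrix(rnorm(n * p), n, p)
  m <- fit_p2e(pairs_from_matrices(P, E, L),
               p2e_spec("ridge", l_p = p, l_e = p, lambda = 0))
  # independent oracle: plain gradient descent on the squared loss
  Xc <- sweep(P, 2, colMeans(P))
  Yc <- sweep(E, 2, colMeans(E))
  W <- matrix(0, p, p)
  step <- 1 / (2 * max(eigen(crossprod(Xc))$values))
  for (i in 1:8000) {
    W <- W - step * 2 * crossprod(Xc, Xc %*% W - Yc)
  }
  expect_lt(max(abs(m$W - W)), 1e-4)
})

test_that("an identity-trained model reproduces the input cycles", {
  set.seed(9)
  pairs <- gen_cycle_pairs(80, seed = 21)
  ident <- lapply(unclass(pairs), function(p) {
    p$ecg <- p$ppg
    p
  })
  ident <- structure(ident, class = "cycle_pairs", L = attr(pairs, "L"),
                     fs = attr(pairs, "fs"), lag = 0L)
  m <- fit_p2e(ident, p2e_spec("ridge", lambda = 1e-6))
  ev <- p2e_evaluate(m, ident)
  expect_lt(ev$summary[["mae"]], 0.01)
})

test_that("test-time synthesis needs only the PPG and its pulse peaks", {
  pairs <- gen_cycle_pairs(200, seed = 31)
  m <- fit_p2e(pairs, p2e_spec("ridge"), seed = 1)
  cfg <- sim_config(duration = 20, hr = 72, noise_sd = 0.02, seed = 77)
  rec <- gen_paired_recording(cfg)
  ppg_f <- wavelet_filter(ppg_signal(channel(rec$ppg, "green"), fs = 125))
  pk <- terma_detect(ppg_f, terma_profile_ppg())
  vl <- detect_valleys(ppg_f, pk)
  ppg_d <- suppressWarnings(detrend_envelope(ppg_f, pk, vl))
  out <- reconstruct_ecg(ppg_d, pk, m)
  # one synthesized beat per complete input cycle
  expect_equal(length(out$cycles), nrow(pk) - 1 -
                 sum(pk$index[1] - round(0.35 * median(diff(pk$index))) < 1))
  expect_s3_class(out$ecg, "ppg_signal")
  expect_equal(n_samples(out$ecg), sum(lengths(out$cycles)))
  expect_error(reconstruct_ecg(ppg_d, pk$index[1], m), "2 pulse peaks")
})

test_that("more DCT coefficients never hurt and saturate early", {
  pairs <- gen_cycle_pairs(260, seed = 41)
  tr <- take_pairs(pairs, 1:200)
  te <- take_pairs(pairs, 201:260)
  tab <- coefficient_sweep(tr, te, c(10, 150, 300), p2e_spec("ridge"))
  expect_true(all(is.finite(unlist(tab[-1]))))
  # nested-model property: full coefficients at least as correlated as 10
  expect_gte(tab$pcorr[tab$l_p == 300], tab$pcorr[tab$l_p == 10] - 0.02)
  # beyond 150 coefficients the gain is marginal
  expect_lt(tab$pcorr[tab$l_p == 300] - tab$pcorr[tab$l_p == 150], 0.05)
  expect_error(coefficient_sweep(tr, te, numeric(0)), "empty")
})

test_that("ffnn training is seed-reproducible and improves on a short run", {
  pairs <- gen_cycle_pairs(150, seed = 51)
  spec <- p2e_spec("ffnn", epochs = 12, patience = 12)
  m1 <- fit_p2e(pairs, spec, seed = 3)
  m2 <- fit_p2e(pairs, spec, seed = 3)
  expect_identical(m1$history, m2$history)
  expect_lt(utils::tail(m1$history$train_mae, 1), m1$history$train_mae[1])
})
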