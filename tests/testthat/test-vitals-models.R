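test_that("DCT front-end obeys its transform identities", {
  L <- 64
  seg <- rep(3, L)
  co <- frontend_apply(seg, frontend_spec("dct"))
  expect_equal(co[1], 3 * sqrt(L), tolerance = 1e-9)
  expect_lt(max(abs(co[-1])), 1e-9)
  # skip connection on zero input stays zero (linearity)
  z <- frontend_apply(rep(0, L), frontend_spec("dct", add_skip = TRUE))
  expect_true(all(z == 0))
  # array form with skip: x + DCT(x), same shape
  x <- array(rnorm(4 * L), dim = c(4, L, 1))
  fe <- frontend_apply(x, frontend_spec("dct", add_skip = TRUE))
  expect_equal(dim(fe), dim(x))
  expect_equal(fe[2, , 1],
               x[2, , 1] + frontend_apply(x[2, , 1], frontend_spec("dct")))
})

test_that("STFT of a pure tone peaks at its frequency in every frame", {
  fs <- 125
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  tone <- sin(2 * pi * 1.25 * t)
  m <- frontend_apply(tone, frontend_spec("stft", window = 256, hop = 128),
                      fs = fs)
  freq <- attr(m, "freq")
  bin <- fs / 256
  for (i in seq_len(nrow(m))) {
    expect_lt(abs(freq[which.max(m[i, ])] - 1.25), bin + 1e-9)
  }
  expect_error(frontend_spec("stft", add_skip = TRUE), "add_skip")
})

test_that("models build with the requested output dimension", {
  # joint configuration stacks all three vitals in one output vector
  b3 <- build_vitals_model(vitals_model_spec("mt_net", n_out = 3),
                           in_len = 300, in_ch = 1, fs = 30)
  x <- array(rnorm(4 * 300 * 1), dim = c(4, 300, 1))
  fe <- frontend_apply(x, vitals_model_spec("mt_net", n_out = 3)$frontend, 30)
  out <- nn_forward(b3$net, fe)
  expect_equal(dim(out), c(4, 3))
  expect_true(all(is.finite(out)))
})

test_that("cnn_net forward pass is finite on a 10 s, 3-channel batch", {
  spec <- vitals_model_spec("cnn_net", n_out = 1)
  b <- build_vitals_model(spec, in_len = 300, in_ch = 3, fs = 30)
  x <- array(rnorm(8 * 300 * 3), dim = c(8, 300, 3))
  fe <- frontend_apply(x, spec$frontend, 30)
  out <- nn_forward(b$net, fe)
  expect_true(all(is.finite(out)))
  expect_gt(b$n_params, 0)
})

test_that("vit_net forward pass is finite and token count is honoured", {
  spec <- vitals_model_spec("vit_net", n_out = 1, n_tokens = 8,
                            d_model = 16, n_blocks = 1)
  b <- build_vitals_model(spec, in_len = 300, in_ch = 1, fs = 30)
  x <- array(rnorm(4 * 300), dim = c(4, 300, 1))
  fe <- frontend_apply(x, spec$frontend, 30)
  out <- nn_forward(b$net, fe)
  expect_equal(dim(out), c(4, 1))
  expect_true(all(is.finite(out)))
})

test_that("doubling the conv filters strictly increases the parameter count", {
  set.seed(1)
  small <- build_vitals_model(vitals_model_spec("mt_net"), 300, 1, 30)
  big <- build_vitals_model(
    vitals_model_spec("mt_net", conv_filters = c(32, 64, 128)), 300, 1, 30)
  expect_gt(big$n_params, small$n_params)
})

test_that("a compact model recovers heart rate from synthetic segments", {
  ds <- gen_vitals_dataset(n_subjects = 8, duration_each = 60, fs = 25,
                           w_s = 8, vitals = "hr", seed = 21)
  tr <- vitals_train_spec(epochs = 12, patience = 6, seed = 21,
                          batch_size = 64)
  m <- train_vitals(ds, vitals_model_spec("mt_net", n_out = 1), tr)
  expect_true(is.finite(m$test_mae))
  expect_lt(m$test_mae, 8) # coarse sanity at this reduced problem size
  # predictions carry physical units and the vital name
  pred <- predict_vitals(m, ds)
  expect_equal(colnames(pred), "hr")
  expect_true(all(pred > 20 & pred < 220))
})

test_that("subject-wise holdout is disjoint and reproducible", {
  set.seed(9)
  segs <- array(rnorm(200 * 16), dim = c(200, 16, 1))
  ds <- structure(list(
    segments = segs, labels = matrix(runif(200, 60, 100), ncol = 1,
                                     dimnames = list(NULL, "hr")),
    subject = rep(1:20, each = 10), w_s = 4, fs = 4, ch = 1, vitals = "hr"
  ), class = "segment_dataset")
  sp <- lesso_split(ds, k = 5, seed = 3)
  expect_length(sp$subjects, 5)
  expect_length(unique(sp$train$subject), 15)
  expect_length(intersect(unique(sp$train$subject), sp$subjects), 0)
  sp2 <- lesso_split(ds, k = 5, seed = 3)
  expect_identical(sp$subjects, sp2$subjects)
  expect_error(lesso_split(ds, k = 20, seed = 1), "k \\+ 1")
})

test_that("LESSO summary equals an independent per-subject loop", {
  ds <- gen_vitals_dataset(n_subjects = 7, duration_each = 40, fs = 25,
                           w_s = 8, vitals = "hr", seed = 31)
  tr <- vitals_train_spec(epochs = 4, patience = 3, seed = 31,
                          batch_size = 64, test_frac = 0)
  res <- lesso_evaluate(ds, vitals_model_spec("mt_net", n_out = 1), tr,
                        k = 2, seed = 5)
  # recompute mu and sigma from the per-subject table by explicit loop
  v <- res$per_subject[[1]]
  mu <- sum(v) / length(v)
  sigma <- sqrt(sum((v - mu)^2) / length(v))
  expect_equal(res$mu[["hr"]], mu)
  expect_equal(res$sigma[["hr"]], sigma)
})

test_that("window-size search reports finite MAE and a matching SAE", {
  source <- function(w_s) {
    gen_vitals_dataset(n_subjects = 4, duration_each = 50, fs = 25,
                       w_s = w_s, vitals = "hr", seed = 41)
  }
  tr <- vitals_train_spec(epochs = 3, patience = 3, seed = 41,
                          batch_size = 64)
  tab <- window_size_search(source, c(4, 8),
                            vitals_model_spec("mt_net", n_out = 1), tr)
  expect_equal(nrow(tab), 2)
  expect_true(all(is.finite(tab$mae)))
  expect_true(all(is.finite(tab$sae)))
  expect_true(all(tab$sae >= 0))
  expect_error(window_size_search(source, numeric(0),
                                  vitals_model_spec("mt_net")), "empty")
})
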