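test_that("captions template deterministically and round-trip exactly", {
  cap <- make_caption(list(hr = 72, spo2 = 97, rr = 16))
  expect_match(cap, "HR is 72 beats/min")
  expect_match(cap, "SpO2 is 97 %", fixed = TRUE)
  expect_match(cap, "RR is 16 breaths/min")
  set.seed(1)
  for (i in 1:100) {
    v <- list(hr = round(runif(1, 40, 180), 2),
              spo2 = round(runif(1, 70, 100), 1),
              rr = round(runif(1, 6, 40)))
    expect_identical(parse_caption(make_caption(v)), v)
  }
  expect_error(make_caption(list()), "no vitals")
})

test_that("blood-pressure fields parse when asked and are ignored otherwise", {
  cap <- make_caption(list(hr = 70, spo2 = 96, rr = 14, sbp = 121, dbp = 81))
  expect_match(cap, "SBP is 121 mmHg")
  only_vitals <- parse_caption(cap, fields = c("hr", "spo2", "rr"))
  expect_named(only_vitals, c("hr", "spo2", "rr"))
  expect_equal(parse_caption(cap, fields = c("sbp", "dbp")),
               list(sbp = 121, dbp = 81))
})

test_that("the default encoder geometry flattens to 9728 features", {
  expect_equal(ppgvitals:::clip_flatten_size(clip_spec()), 9728)
  # valid-convolution arithmetic: 1250 -> 1241 with kernel 10 at stride 1
  expect_equal(1250 - 10 + 1, 1241)
  lens <- Reduce(function(len, i) {
    spec <- clip_spec()
    out <- len - spec$conv_kernels[i] + 1
    if (i %in% spec$pool_after) out <- out %/% 2
    out
  }, 1:4, accumulate = TRUE, init = 1250)
  expect_equal(lens[-1], c(620, 308, 306, 304))
})

test_that("identical segments produce identical embeddings", {
  set.seed(2)
  spec <- clip_spec(input_len = 120, conv_filters = c(4, 8),
                    conv_kernels = c(8, 3), pool_after = 1,
                    embed_dim = 16, d_text = 8)
  corpus <- lapply(1:8, function(i) {
    list(segment = rnorm(120), caption = make_caption(list(hr = 60 + i)))
  })
  m <- pretrain_clip(corpus, spec, epochs = 2, batch_size = 4, seed = 3)
  seg <- corpus[[1]]$segment
  e1 <- encode_ppg(m, seg)
  e2 <- encode_ppg(m, seg)
  expect_identical(e1, e2)
  expect_equal(sqrt(sum(e1^2)), 1, tolerance = 1e-6) # unit norm
})

test_that("contrastive pretraining separates matched pairs", {
  corpus <- gen_caption_corpus(120, fs = 25, w_s = 10, seed = 3)
  spec <- clip_spec(input_len = 250, conv_filters = c(8, 8, 16),
                    conv_kernels = c(10, 5, 3), pool_after = c(1, 2),
                    embed_dim = 64, d_text = 32)
  m <- pretrain_clip(corpus[1:96], spec, epochs = 25, batch_size = 32,
                     seed = 2)
  expect_lt(utils::tail(m$history, 1), m$history[1])
  # held-out batch: diagonal (matched) similarity above off-diagonal
  segs <- t(vapply(corpus[97:120], `[[`, numeric(250), "segment"))
  caps <- vapply(corpus[97:120], `[[`, character(1), "caption")
  S <- encode_ppg(m, segs) %*% t(encode_text(m, caps))
  expect_gt(mean(diag(S)), mean(S[row(S) != col(S)]))
})

test_that("pretraining is reproducible for a fixed seed", {
  corpus <- gen_caption_corpus(24, fs = 25, w_s = 4, seed = 5)
  spec <- clip_spec(input_len = 100, conv_filters = c(4, 8),
                    conv_kernels = c(8, 3), pool_after = 1,
                    embed_dim = 16, d_text = 8)
  m1 <- pretrain_clip(corpus, spec, epochs = 4, batch_size = 8, seed = 9)
  m2 <- pretrain_clip(corpus, spec, epochs = 4, batch_size = 8, seed = 9)
  expect_equal(utils::tail(m1$history, 1), utils::tail(m2$history, 1),
               tolerance = 1e-6)
  expect_error(pretrain_clip(corpus, spec, batch_size = 1), "at least 2")
  expect_error(pretrain_clip(corpus[1], spec), "at least 2")
})

test_that("retrieval ranks by dot product with forced embeddings", {
  # one bank embedding equals the query, the rest are orthogonal
  q <- c(1, 0, 0, 0)
  bank_emb <- rbind(c(0, 1, 0, 0), c(1, 0, 0, 0), c(0, 0, 1, 0))
  expect_equal(clip_rank(q, bank_emb, k = 1), 2L)
  expect_equal(clip_rank(q, bank_emb, k = 3)[1], 2L)
  # ranking is invariant under global positive scaling
  expect_equal(clip_rank(q, 7 * bank_emb, k = 3), clip_rank(q, bank_emb, 3))
})

test_that("top-k querying averages the parsed captions per vital", {
  set.seed(6)
  spec <- clip_spec(input_len = 100, conv_filters = c(4, 8),
                    conv_kernels = c(8, 3), pool_after = 1,
                    embed_dim = 16, d_text = 8)
  corpus <- lapply(1:8, function(i) {
    list(segment = rnorm(100), caption = make_caption(list(hr = 60 + i)))
  })
  m <- pretrain_clip(corpus, spec, epochs = 2, batch_size = 4, seed = 3)
  # with k equal to the bank size the prediction is the bank mean,
  # whatever the ranking; blood-pressure fields are ignored
  bank <- c(
    make_caption(list(hr = 70, spo2 = 97, rr = 15)),
    make_caption(list(hr = 72, spo2 = 98, rr = 16, sbp = 120, dbp = 80)),
    make_caption(list(hr = 74, spo2 = 99, rr = 17))
  )
  res <- query_vitals(m, rnorm(100), bank, k = 3)
  expect_equal(res$vitals$hr, 72)
  expect_equal(res$vitals$spo2, 98)
  expect_equal(res$vitals$rr, 16)
  expect_false("sbp" %in% names(res$vitals))
  expect_length(res$captions, 3)
  # requesting a vital absent from every caption warns and drops it
  bank_hr <- c(make_caption(list(hr = 70)), make_caption(list(hr = 74)))
  expect_warning(
    r2 <- query_vitals(m, rnorm(100), bank_hr, k = 2,
                       fields = c("hr", "spo2")),
    "spo2"
  )
  expect_equal(r2$vitals$hr, 72)
})
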