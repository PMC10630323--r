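#' Caption templating and parsing for vitals
#'
#' `make_caption()` renders numeric vitals as a deterministic one-line
#' caption with units ("HR is 72 beats/min, SpO2 is 97 %, RR is 16
#' breaths/min", optionally with SBP/DBP in mmHg); `parse_caption()`
#' extracts the numeric values back out by unit-anchored patterns, and the
#' round trip is exact. A parser asked only for a subset of vitals ignores
#' any other fields present in the caption.
#'
#' @param vitals named list/vector with any of `hr`, `spo2`, `rr`, `sbp`,
#'   `dbp`; at least one must be present.
#' @return `make_caption()`: a character scalar. `parse_caption()`: a named
#'   list of the requested vitals found in the text.
#' @export
make_caption <- function(vitals) {
  vitals <- vitals[!vapply(vitals, is.null, logical(1))]
  if (!length(vitals)) stop("no vitals to caption", call. = FALSE)
  fmt <- function(x) format(x, digits = 15, trim = TRUE, scientific = FALSE)
  parts <- character(0)
  if (!is.null(vitals$hr)) parts <- c(parts, paste0("HR is ", fmt(vitals$hr), " beats/min"))
  if (!is.null(vitals$spo2)) parts <- c(parts, paste0("SpO2 is ", fmt(vitals$spo2), " %"))
  if (!is.null(vitals$rr)) parts <- c(parts, paste0("RR is ", fmt(vitals$rr), " breaths/min"))
  if (!is.null(vitals$sbp)) parts <- c(parts, paste0("SBP is ", fmt(vitals$sbp), " mmHg"))
  if (!is.null(vitals$dbp)) parts <- c(parts, paste0("DBP is ", fmt(vitals$dbp), " mmHg"))
  if (!length(parts)) stop("no recognized vitals to caption", call. = FALSE)
  paste(parts, collapse = ", ")
}

#' @rdname make_caption
#' @param text caption string.
#' @param fields which vitals to extract (default `hr`, `spo2`, `rr`).
#' @export
parse_caption <- function(text, fields = c("hr", "spo2", "rr")) {
  patterns <- c(
    hr = "HR is ([-0-9.eE]+) beats/min",
    spo2 = "SpO2 is ([-0-9.eE]+) %",
    rr = "RR is ([-0-9.eE]+) breaths/min",
    sbp = "SBP is ([-0-9.eE]+) mmHg",
    dbp = "DBP is ([-0-9.eE]+) mmHg"
  )
  out <- list()
  for (f in fields) {
    m <- regmatches(text, regexec(patterns[[f]], text))[[1]]
    if (length(m) == 2) out[[f]] <- as.numeric(m[2])
  }
  out
}

#' PPG/text encoder specification for contrastive retrieval
#'
#' The PPG encoder is a 1-D CNN (channels 8, 8, 16, 32; kernels 10, 5, 3,
#' 3; stride 1; max-pool 2 after the first two convolutions) whose flatten
#' width is 9728 for the default 1250-sample input, followed by a
#' projection head (dense to the embedding width, then a residual
#' gelu-dense-dropout block and layer normalization). The text encoder is
#' a trainable token-embedding bag (whitespace/number-aware tokenizer)
#' pooled by the mean and passed through the same projection head shape.
#' Embeddings are L2-normalized.
#'
#' @param input_len PPG segment length in samples (1250 = 10 s at 125 Hz).
#' @param conv_filters,conv_kernels,pool_after convolution stack; pooling
#'   (width 2) follows the blocks listed in `pool_after`.
#' @param embed_dim embedding width (default 256).
#' @param dropout projection-head dropout rate.
#' @param d_text token-embedding width before projection.
#' @return An object of class `clip_spec`.
#' @export
clip_spec <- function(input_len = 1250,
                      conv_filters = c(8, 8, 16, 32),
                      conv_kernels = c(10, 5, 3, 3),
                      pool_after = c(1, 2),
                      embed_dim = 256, dropout = 0.2, d_text = 64) {
  stopifnot(length(conv_filters) == length(conv_kernels))
  structure(list(input_len = input_len, conv_filters = conv_filters,
                 conv_kernels = conv_kernels, pool_after = pool_after,
                 embed_dim = embed_dim, dropout = dropout, d_text = d_text),
            class = "clip_spec")
}

# flatten width implied by the conv stack
clip_flatten_size <- function(spec) {
  len <- spec$input_len
  for (i in seq_along(spec$conv_filters)) {
    len <- len - spec$conv_kernels[i] + 1
    if (i %in% spec$pool_after) len <- len %/% 2
  }
  len * spec$conv_filters[length(spec$conv_filters)]
}

projection_head <- function(n_in, dim, dropout) {
  list(
    layer_dense(n_in, dim),
    layer_residual(list(
      layer_activation("gelu"),
      layer_dense(dim, dim),
      layer_dropout(dropout)
    )),
    layer_layernorm(dim)
  )
}

build_ppg_encoder <- function(spec) {
  layers <- list()
  ch <- 1L
  for (i in seq_along(spec$conv_filters)) {
    layers <- c(layers, list(
      layer_conv1d(ch, spec$conv_filters[i], spec$conv_kernels[i]),
      layer_activation("relu")
    ))
    if (i %in% spec$pool_after) layers <- c(layers, list(layer_maxpool1d(2)))
    ch <- spec$conv_filters[i]
  }
  layers <- c(layers, list(layer_flatten()),
              projection_head(clip_flatten_size(spec), spec$embed_dim,
                              spec$dropout))
  nn_sequential(layers)
}

# whitespace/number-aware tokenizer; numbers survive as single tokens
clip_tokenize <- function(text) {
  toks <- unlist(strsplit(tolower(text), "[ ,]+"))
  toks[nzchar(toks)]
}

clip_vocab <- function(captions) {
  toks <- unique(unlist(lapply(captions, clip_tokenize)))
  c("<unk>", sort(toks))
}

token_ids <- function(text, vocab) {
  i <- match(clip_tokenize(text), vocab)
  i[is.na(i)] <- 1L
  i
}

# L2 row normalization and its backward pass
l2_normalize_rows <- function(z) {
  nrm <- sqrt(rowSums(z^2)) + 1e-12
  list(e = z / nrm, nrm = nrm)
}

l2_normalize_backward <- function(de, e, nrm) {
  (de - e * rowSums(de * e)) / nrm
}

#' Encode PPG segments with a fitted contrastive model
#'
#' @param model a [pretrain_clip()] result.
#' @param segments matrix `(n, input_len)` or a single numeric vector.
#' @return Matrix `(n, embed_dim)` of unit-norm embeddings.
#' @export
encode_ppg <- function(model, segments) {
  if (is.null(dim(segments))) segments <- matrix(segments, nrow = 1)
  x <- array(segments, dim = c(nrow(segments), ncol(segments), 1))
  z <- nn_forward(model$ppg_net, x, training = FALSE)
  l2_normalize_rows(z)$e
}

#' Encode captions with a fitted contrastive model
#'
#' @param model a [pretrain_clip()] result.
#' @param captions character vector.
#' @return Matrix `(n, embed_dim)` of unit-norm embeddings.
#' @export
encode_text <- function(model, captions) {
  pooled <- t(vapply(captions, function(cap) {
    ids <- token_ids(cap, model$vocab)
    colMeans(model$emb$params$E[ids, , drop = FALSE])
  }, numeric(ncol(model$emb$params$E))))
  z <- nn_forward(model$text_proj, pooled, training = FALSE)
  l2_normalize_rows(z)$e
}

#' Contrastive pretraining of the PPG and caption encoders
#'
#' Optimizes the symmetric cross-entropy over the in-batch similarity
#' matrix (scaled by a learnable temperature): each PPG segment must
#' retrieve its own caption among the batch and vice versa. Training is
#' seed-reproducible in a single thread.
#'
#' @param corpus list of records `list(segment, caption, ...)` as produced
#'   by [gen_caption_corpus()]; at least 2.
#' @param spec a [clip_spec()] matching the segment length.
#' @param epochs training epochs.
#' @param batch_size in-batch negatives per step (minimum 2).
#' @param lr Adam learning rate.
#' @param seed RNG seed.
#' @param verbose print loss every this many epochs (0 = silent).
#' @return An object of class `clip_model` with the two encoders, the
#'   vocabulary, the learned temperature, and the per-epoch loss history.
#' @export
pretrain_clip <- function(corpus, spec = clip_spec(), epochs = 20,
                          batch_size = 32, lr = 1e-3, seed = 1L,
                          verbose = 0) {
  if (length(corpus) < 2) stop("need at least 2 (segment, caption) pairs", call. = FALSE)
  if (batch_size < 2) stop("contrastive batches need at least 2 pairs", call. = FALSE)
  set.seed(seed)
  segs <- t(vapply(corpus, function(r) as.numeric(r$segment),
                   numeric(length(corpus[[1]]$segment))))
  if (ncol(segs) != spec$input_len) {
    stop("segment length does not match spec$input_len", call. = FALSE)
  }
  captions <- vapply(corpus, `[[`, character(1), "caption")
  vocab <- clip_vocab(captions)
  ids <- lapply(captions, token_ids, vocab = vocab)
  ppg_net <- build_ppg_encoder(spec)
  emb <- new_layer("embedding")
  emb$params$E <- xavier_init(length(vocab), spec$d_text,
                              dims = c(length(vocab), spec$d_text))
  text_proj <- nn_sequential(projection_head(spec$d_text, spec$embed_dim,
                                             spec$dropout))
  temp <- new_layer("temperature")
  temp$params$s <- log(1 / 0.07) # standard initial temperature
  layers <- c(flatten_layers(ppg_net$layers), list(emb),
              flatten_layers(text_proj$layers), list(temp))
  n <- length(corpus)
  history <- numeric(epochs)
  step <- 0
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    nb <- 0
    for (b0 in seq(1, n, by = batch_size)) {
      bi <- ord[b0:min(b0 + batch_size - 1, n)]
      B <- length(bi)
      if (B < 2) next
      xb <- array(segs[bi, , drop = FALSE], dim = c(B, spec$input_len, 1))
      zp <- nn_forward(ppg_net, xb, training = TRUE)
      pooled <- t(vapply(ids[bi], function(ii) {
        colMeans(emb$params$E[ii, , drop = FALSE])
      }, numeric(spec$d_text)))
      zt <- nn_forward(text_proj, pooled, training = TRUE)
      np <- l2_normalize_rows(zp)
      nt <- l2_normalize_rows(zt)
      scale <- exp(temp$params$s)
      sim <- tcrossprod(np$e, nt$e)
      logits <- sim * scale
      sm_r <- softmax_rows(logits)
      sm_c <- t(softmax_rows(t(logits)))
      eye <- diag(B)
      loss <- -0.5 * mean(log(diag(sm_r) + 1e-12)) -
        0.5 * mean(log(diag(sm_c) + 1e-12))
      if (!is.finite(loss)) stop("NaN loss in contrastive pretraining", call. = FALSE)
      ep_loss <- ep_loss + loss
      nb <- nb + 1
      dlogits <- (0.5 * (sm_r - eye) + 0.5 * (sm_c - eye)) / B
      temp$grads$s <- sum(dlogits * sim) * scale
      dnp <- (dlogits %*% nt$e) * scale
      dnt <- (crossprod(dlogits, np$e)) * scale
      dzp <- l2_normalize_backward(dnp, np$e, np$nrm)
      dzt <- l2_normalize_backward(dnt, nt$e, nt$nrm)
      nn_backward(ppg_net, dzp)
      dpooled <- nn_backward(text_proj, dzt)
      dE <- emb$params$E * 0
      for (j in seq_len(B)) {
        ii <- ids[[bi[j]]]
        contrib <- dpooled[j, ] / length(ii)
        for (tok in unique(ii)) {
          dE[tok, ] <- dE[tok, ] + contrib * sum(ii == tok)
        }
      }
      emb$grads$E <- dE
      step <- step + 1
      adam_update(layers, lr, step)
    }
    history[ep] <- ep_loss / max(nb, 1)
    if (verbose > 0 && ep %% verbose == 0) {
      message(sprintf("clip epoch %d: loss %.4f temp %.3f",
                      ep, history[ep], exp(temp$params$s)))
    }
  }
  structure(list(ppg_net = ppg_net, emb = emb, text_proj = text_proj,
                 vocab = vocab, temperature = exp(temp$params$s),
                 spec = spec, history = history),
            class = "clip_model")
}

softmax_rows <- function(m) {
  m <- m - apply(m, 1, max)
  e <- exp(m)
  e / rowSums(e)
}

#' Rank caption-bank embeddings against a query embedding
#'
#' @param query_emb unit-norm query embedding (vector).
#' @param bank_emb matrix of caption embeddings (one row per caption).
#' @param k how many to return.
#' @return Integer indices of the top-`k` captions by dot product.
#' @export
clip_rank <- function(query_emb, bank_emb, k = 3) {
  scores <- as.numeric(bank_emb %*% as.numeric(query_emb))
  order(scores, decreasing = TRUE)[seq_len(min(k, length(scores)))]
}

#' Retrieve vitals for a PPG segment by top-k caption matching
#'
#' Embeds the query segment, ranks every caption in the bank by embedding
#' dot product, parses the numeric vitals out of the top-`k` captions, and
#' averages each requested vital over the captions that contain it. Fields
#' not requested (e.g. blood pressure in a mixed-corpus bank) are ignored.
#'
#' @param model a fitted [pretrain_clip()] model.
#' @param segment numeric vector of `spec$input_len` samples.
#' @param bank character vector of candidate captions.
#' @param k top captions to average over (default 3).
#' @param fields vitals to extract (default `hr`, `spo2`, `rr`).
#' @param bank_emb optional precomputed [encode_text()] matrix for `bank`.
#' @return List with `vitals` (named list of averaged predictions;
#'   requested vitals absent from every top caption are dropped with a
#'   warning) and `captions` (the top-k caption strings).
#' @export
query_vitals <- function(model, segment, bank, k = 3,
                         fields = c("hr", "spo2", "rr"), bank_emb = NULL) {
  if (!length(bank)) stop("empty caption bank", call. = FALSE)
  if (is.null(bank_emb)) bank_emb <- encode_text(model, bank)
  q <- encode_ppg(model, segment)
  top <- clip_rank(q[1, ], bank_emb, k = k)
  parsed <- lapply(bank[top], parse_caption, fields = fields)
  vitals <- list()
  for (f in fields) {
    vals <- unlist(lapply(parsed, `[[`, f))
    if (length(vals)) {
      vitals[[f]] <- mean(vals)
    } else {
      warning("no top caption contains a value for ", f)
    }
  }
  list(vitals = vitals, captions = bank[top])
}
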