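#' Spectral front-end specification
#'
#' The fixed (non-trainable) transform applied to each PPG segment before
#' the trainable stack: a short-time Fourier magnitude image (`stft`), a
#' type-II orthonormal DCT optionally added back onto the input
#' (`dct` with `add_skip`, which requires equal input/output lengths), or
#' the identity (`none`).
#'
#' @param mode `"stft"`, `"dct"` or `"none"`.
#' @param window,hop STFT window and hop, samples.
#' @param add_skip add the input to the transform output (DCT mode).
#' @return An object of class `frontend_spec`.
#' @export
frontend_spec <- function(mode = c("none", "stft", "dct"), window = 128,
                          hop = window %/% 2, add_skip = FALSE) {
  mode <- match.arg(mode)
  if (add_skip && mode != "dct") {
    stop("add_skip is only valid for the dct front-end", call. = FALSE)
  }
  structure(list(mode = mode, window = window, hop = hop,
                 add_skip = add_skip), class = "frontend_spec")
}

#' Apply a spectral front-end to a segment or a segment array
#'
#' @param x numeric vector (one single-channel segment) or array
#'   `(N, T, ch)` of segments.
#' @param spec a [frontend_spec()].
#' @param fs sampling rate of the segments, Hz (needed for STFT bin
#'   labelling).
#' @return For a vector input: a vector (dct/none) or `frames x bins`
#'   matrix (stft). For an array input: the transformed array, STFT
#'   channels stacked along the feature axis.
#' @export
frontend_apply <- function(x, spec, fs = NULL) {
  if (is.null(dim(x))) {
    return(frontend_one(as.numeric(x), spec, fs))
  }
  d <- dim(x)
  N <- d[1]; Tn <- d[2]; ch <- d[3]
  if (spec$mode == "none") return(x)
  if (spec$mode == "dct") {
    C <- dct_matrix(Tn)
    out <- x
    for (c in seq_len(ch)) {
      seg <- matrix(x[, , c], N, Tn)
      tr <- seg %*% t(C)
      out[, , c] <- if (spec$add_skip) seg + tr else tr
    }
    return(out)
  }
  # stft: transform channel by channel, stack bins over channels
  probe <- stft_mag(x[1, , 1], fs %||% 1, spec$window, spec$hop)
  nf <- nrow(probe); nb <- ncol(probe)
  out <- array(0, dim = c(N, nf, nb * ch))
  for (i in seq_len(N)) {
    for (c in seq_len(ch)) {
      out[i, , (c - 1) * nb + seq_len(nb)] <-
        stft_mag(x[i, , c], fs %||% 1, spec$window, spec$hop)
    }
  }
  out
}

frontend_one <- function(v, spec, fs) {
  switch(spec$mode,
    none = v,
    dct = {
      tr <- dct_truncate(v, length(v))
      if (spec$add_skip) v + tr else tr
    },
    stft = stft_mag(v, fs %||% 1, spec$window, spec$hop)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Vitals-Net model specification
#'
#' Architecture description of the compact regressors mapping a PPG
#' segment to one or more vitals:
#' * `cnn_net` - STFT front-end, 1-D convolution blocks over the frame
#'   axis, then a dense head; batch normalization and dropout follow the
#'   flattening layer and every dense layer.
#' * `mt_net` - DCT front-end with an additive skip (input + DCT), the
#'   same convolution blocks, and a relu fully-connected head.
#' * `vit_net` - STFT front-end patchified into tokens feeding a small
#'   transformer encoder (pre-layernorm attention and MLP blocks) with
#'   mean-token pooling.
#'
#' @param name `"cnn_net"`, `"mt_net"` or `"vit_net"`.
#' @param frontend a [frontend_spec()]; defaults per model name.
#' @param conv_filters,conv_kernel,pool convolution stack (per-block
#'   filters, shared kernel size, max-pool width).
#' @param dense_units width of the dense head.
#' @param dropout dropout rate after flatten/dense layers.
#' @param n_out output dimension: 1 for vital-specific training, 3 for
#'   joint training.
#' @param n_tokens,d_model,n_blocks transformer shape for `vit_net`.
#' @return An object of class `vitals_model_spec`.
#' @export
vitals_model_spec <- function(name = c("mt_net", "cnn_net", "vit_net"),
                              frontend = NULL,
                              conv_filters = c(16, 32, 64),
                              conv_kernel = 5, pool = 2,
                              dense_units = 64, dropout = 0.2, n_out = 1,
                              n_tokens = 16, d_model = 64, n_blocks = 2) {
  name <- match.arg(name)
  if (is.null(frontend)) {
    # short window / dense hop so even 10 s segments at video frame rates
    # leave enough STFT frames for the convolution or token stack
    frontend <- switch(name,
      cnn_net = frontend_spec("stft", window = 32, hop = 4),
      mt_net = frontend_spec("dct", add_skip = TRUE),
      vit_net = frontend_spec("stft", window = 32, hop = 4)
    )
  }
  stopifnot(dropout >= 0, dropout < 1, n_out >= 1)
  structure(list(name = name, frontend = frontend,
                 conv_filters = conv_filters, conv_kernel = conv_kernel,
                 pool = pool, dense_units = dense_units, dropout = dropout,
                 n_out = n_out, n_tokens = n_tokens, d_model = d_model,
                 n_blocks = n_blocks), class = "vitals_model_spec")
}

#' Training specification for the vitals regressors
#'
#' @param batch_size mini-batch size (default 128).
#' @param epochs maximum epochs (default 1000; early stopping applies).
#' @param lr initial learning rate.
#' @param val_frac,test_frac validation and held-out test fractions.
#' @param patience early-stopping patience on the validation MAE.
#' @param lr_factor plateau learning-rate decay factor.
#' @param scale_labels z-score each vital before the MAE loss (predictions
#'   are mapped back to physical units).
#' @param seed RNG seed.
#' @return An object of class `vitals_train_spec`.
#' @export
vitals_train_spec <- function(batch_size = 128, epochs = 1000, lr = 1e-3,
                              val_frac = 0.15, test_frac = 0.10,
                              patience = 20, lr_factor = 0.1,
                              scale_labels = TRUE, seed = 1L) {
  stopifnot(val_frac + test_frac < 1)
  structure(list(batch_size = batch_size, epochs = epochs, lr = lr,
                 val_frac = val_frac, test_frac = test_frac,
                 patience = patience, lr_factor = lr_factor,
                 scale_labels = scale_labels, seed = as.integer(seed)),
            class = "vitals_train_spec")
}

# assemble the trainable nn for an already-front-ended input of shape
# (length, channels)
build_vitals_net <- function(spec, in_len, in_ch) {
  if (spec$name %in% c("cnn_net", "mt_net")) {
    layers <- list()
    ch <- in_ch
    len <- in_len
    for (f in spec$conv_filters) {
      if (len < spec$conv_kernel) {
        stop(sprintf("conv block with %d filters: input length %d shorter than kernel %d",
                     f, len, spec$conv_kernel), call. = FALSE)
      }
      layers <- c(layers, list(
        layer_conv1d(ch, f, spec$conv_kernel),
        layer_activation("relu"),
        layer_maxpool1d(spec$pool)
      ))
      len <- (len - spec$conv_kernel + 1) %/% spec$pool
      ch <- f
    }
    flat <- len * ch
    if (flat < 1) stop("segment too short for the convolution stack", call. = FALSE)
    head_act <- if (spec$name == "mt_net") "relu" else "relu"
    layers <- c(layers, list(
      layer_flatten(),
      layer_batchnorm(flat),
      layer_dropout(spec$dropout),
      layer_dense(flat, spec$dense_units),
      layer_activation(head_act),
      layer_batchnorm(spec$dense_units),
      layer_dropout(spec$dropout),
      layer_dense(spec$dense_units, spec$n_out)
    ))
    nn_sequential(layers)
  } else { # vit_net
    patch_len <- in_len %/% spec$n_tokens
    if (patch_len < 1) stop("too few frames for the requested token count", call. = FALSE)
    d <- spec$d_model
    layers <- list(
      layer_patchify(spec$n_tokens),
      layer_dense(patch_len * in_ch, d)
    )
    for (b in seq_len(spec$n_blocks)) {
      layers <- c(layers, list(
        layer_residual(list(layer_layernorm(d), layer_attention(d))),
        layer_residual(list(layer_layernorm(d), layer_dense(d, 2 * d),
                            layer_activation("gelu"), layer_dense(2 * d, d)))
      ))
    }
    layers <- c(layers, list(
      layer_layernorm(d),
      layer_meanpool_tokens(),
      layer_dropout(spec$dropout),
      layer_dense(d, spec$n_out)
    ))
    nn_sequential(layers)
  }
}

#' Build a vitals regressor for a given segment geometry
#'
#' Instantiates the trainable network for segments of `in_len` samples and
#' `in_ch` channels (dimensions after the front-end are derived
#' automatically) and reports its parameter count.
#'
#' @param spec a [vitals_model_spec()].
#' @param in_len segment length in samples (before the front-end).
#' @param in_ch channel count.
#' @param fs segment sampling rate, Hz.
#' @return List with `net` (an `nn_model`), `spec`, `n_params`, and the
#'   front-ended input geometry (`fe_len`, `fe_ch`).
#' @export
build_vitals_model <- function(spec, in_len, in_ch, fs) {
  probe <- array(0, dim = c(1, in_len, in_ch))
  fe <- frontend_apply(probe, spec$frontend, fs)
  fe_len <- dim(fe)[2]
  fe_ch <- dim(fe)[3]
  net <- build_vitals_net(spec, fe_len, fe_ch)
  list(net = net, spec = spec, n_params = count_params(net),
       fe_len = fe_len, fe_ch = fe_ch)
}

#' Train a vitals regressor on a segment dataset
#'
#' Applies the model's spectral front-end to every segment, z-scores the
#' inputs globally and (optionally) each vital's labels, holds out a test
#' fraction, and trains under the batch-mean absolute-error criterion with
#' Adam, plateau learning-rate decay, and early stopping with best-weight
#' restoration.
#'
#' @param ds a `segment_dataset` (see [segment_signal()]).
#' @param spec a [vitals_model_spec()]; `n_out` must equal the number of
#'   vitals in `ds`.
#' @param tr a [vitals_train_spec()].
#' @param verbose print a progress line every this many epochs.
#' @return An object of class `vitals_model`: the fitted network plus
#'   normalization constants, training `history`, and `test_mae` (per
#'   vital, physical units) on the held-out fraction.
#' @export
train_vitals <- function(ds, spec, tr = vitals_train_spec(), verbose = 0) {
  stopifnot(inherits(ds, "segment_dataset"))
  if (spec$n_out != ncol(ds$labels)) {
    stop("spec$n_out must match the number of vitals in the dataset", call. = FALSE)
  }
  n <- dim(ds$segments)[1]
  if (n == 0) stop("empty dataset", call. = FALSE)
  set.seed(tr$seed)
  x <- frontend_apply(ds$segments, spec$frontend, ds$fs)
  x_center <- mean(x)
  x_scale <- stats::sd(x)
  if (x_scale == 0) x_scale <- 1
  x <- (x - x_center) / x_scale
  y <- ds$labels
  if (tr$scale_labels) {
    y_center <- colMeans(y)
    y_scale <- apply(y, 2, stats::sd)
    y_scale[y_scale == 0] <- 1
  } else {
    y_center <- rep(0, ncol(y))
    y_scale <- rep(1, ncol(y))
  }
  ys <- sweep(sweep(y, 2, y_center), 2, y_scale, "/")
  ti <- if (tr$test_frac > 0) sample.int(n, max(1L, round(tr$test_frac * n))) else integer(0)
  tri <- setdiff(seq_len(n), ti)
  built <- build_vitals_model(spec, dim(ds$segments)[2], ds$ch, ds$fs)
  fit <- nn_train(built$net, index_rows(x, tri), ys[tri, , drop = FALSE],
                  epochs = tr$epochs, batch_size = tr$batch_size, lr = tr$lr,
                  val_frac = tr$val_frac / (1 - tr$test_frac),
                  patience = tr$patience,
                  schedule = lr_schedule_plateau(tr$lr_factor, tr$patience %/% 2),
                  seed = tr$seed, verbose = verbose)
  model <- structure(list(
    net = fit$model, spec = spec, tr = tr,
    x_center = x_center, x_scale = x_scale,
    y_center = y_center, y_scale = y_scale,
    fs = ds$fs, w_s = ds$w_s, ch = ds$ch, vitals = ds$vitals,
    n_params = built$n_params, history = fit$history
  ), class = "vitals_model")
  if (length(ti)) {
    pred <- predict_vitals(model, subset_segments(ds, ti))
    model$test_mae <- colMeans(abs(pred - y[ti, , drop = FALSE]))
  }
  model
}

#' Predict vitals for a segment dataset or raw segment array
#'
#' @param model a fitted `vitals_model`.
#' @param ds a `segment_dataset` or array `(N, T, ch)`.
#' @return Matrix `(N, n_vitals)` of predictions in physical units.
#' @export
predict_vitals <- function(model, ds) {
  segs <- if (inherits(ds, "segment_dataset")) ds$segments else ds
  x <- frontend_apply(segs, model$spec$frontend, model$fs)
  x <- (x - model$x_center) / model$x_scale
  pred <- nn_predict(model$net, x)
  out <- sweep(sweep(pred, 2, model$y_scale, "*"), 2, model$y_center, "+")
  colnames(out) <- model$vitals
  out
}

#' Leave-several-subjects-out split
#'
#' Holds out `k` randomly chosen subjects entirely: none of their segments
#' appear in the training/validation portion, and each held-out subject is
#' returned separately so per-subject errors can be summarized as a mean
#' and standard deviation across subjects.
#'
#' @param ds a `segment_dataset` whose `subject` field is populated.
#' @param k number of held-out subjects (default 5).
#' @param seed RNG seed for the subject draw.
#' @return List with `train` (segment_dataset), `heldout` (named list of
#'   per-subject segment_datasets), and `subjects` (the held-out ids).
#' @export
lesso_split <- function(ds, k = 5, seed = 1L) {
  stopifnot(inherits(ds, "segment_dataset"))
  subs <- unique(ds$subject)
  if (any(is.na(subs))) stop("subject labels missing", call. = FALSE)
  if (length(subs) < k + 1) stop("need at least k + 1 subjects", call. = FALSE)
  set.seed(seed)
  held <- sample(subs, k)
  train <- subset_segments(ds, which(!ds$subject %in% held))
  heldout <- lapply(held, function(s) subset_segments(ds, which(ds$subject == s)))
  names(heldout) <- as.character(held)
  list(train = train, heldout = heldout, subjects = held)
}

#' Subject-wise evaluation on a LESSO split
#'
#' Trains on the retained subjects and reports each held-out subject's MAE
#' plus the mean and standard deviation across subjects.
#'
#' @param ds a `segment_dataset` with subjects.
#' @param spec,tr model and training specifications.
#' @param k held-out subject count.
#' @param seed seed for the split (training uses `tr$seed`).
#' @return List with `model`, `per_subject` (data.frame subject x vital
#'   MAE), `mu`, `sigma` (per-vital mean/sd across subjects).
#' @export
lesso_evaluate <- function(ds, spec, tr = vitals_train_spec(), k = 5,
                           seed = 1L) {
  sp <- lesso_split(ds, k = k, seed = seed)
  model <- train_vitals(sp$train, spec, tr)
  per <- vapply(sp$heldout, function(d) {
    pred <- predict_vitals(model, d)
    colMeans(abs(pred - d$labels))
  }, numeric(length(ds$vitals)))
  # one row per held-out subject, one column per vital
  per <- matrix(per, ncol = length(ds$vitals), byrow = TRUE,
                dimnames = list(names(sp$heldout), ds$vitals))
  mu <- colMeans(per)
  sigma <- apply(per, 2, function(v) sqrt(sum((v - mean(v))^2) / length(v)))
  list(model = model, per_subject = as.data.frame(per), mu = mu, sigma = sigma)
}

#' Window-size search
#'
#' Re-segments, retrains and scores the model for every window length in
#' the grid, recording the held-out MAE and SAE (standard deviation of the
#' absolute errors) per vital. Short windows suit the fast vitals (heart
#' rate, SpO2); respiratory rate needs windows long enough to span several
#' breaths, so its default grids extend to 32 s.
#'
#' @param source function taking a window length `w_s` (seconds) and
#'   returning a `segment_dataset`.
#' @param grid vector of window lengths, seconds.
#' @param spec,tr model and training specifications (reduced `tr$epochs`
#'   is customary here).
#' @return data.frame with one row per (w_s, vital): columns `w_s`,
#'   `vital`, `mae`, `sae`.
#' @export
window_size_search <- function(source, grid, spec, tr = vitals_train_spec()) {
  if (!length(grid)) stop("empty window grid", call. = FALSE)
  rows <- list()
  for (w in grid) {
    ds <- source(w)
    n <- dim(ds$segments)[1]
    set.seed(tr$seed)
    ti <- sample.int(n, max(1L, round(tr$test_frac * n)))
    tr_w <- tr
    tr_w$test_frac <- 0
    model <- train_vitals(subset_segments(ds, setdiff(seq_len(n), ti)),
                          spec, tr_w)
    test <- subset_segments(ds, ti)
    pred <- predict_vitals(model, test)
    for (v in seq_along(ds$vitals)) {
      ms <- mae_sae(test$labels[, v], pred[, v])
      rows[[length(rows) + 1]] <- data.frame(
        w_s = w, vital = ds$vitals[v], mae = ms[["mae"]], sae = ms[["sae"]]
      )
    }
  }
  do.call(rbind, rows)
}

#' Generate a multi-recording synthetic vitals dataset
#'
#' Synthesizes one recording per subject with subject-specific vitals,
#' wavelet-filters the chosen channels, and segments everything into a
#' single labelled dataset — the synthetic stand-in for a fingertip-video
#' training corpus.
#'
#' @param n_subjects number of recordings/subjects.
#' @param duration_each seconds per recording.
#' @param fs sampling rate, Hz (30 matches a phone camera; 125 a pulse
#'   oximeter).
#' @param w_s window length, seconds.
#' @param vitals subset of `c("hr", "spo2", "rr")` to keep as labels.
#' @param channels PPG channels to keep (`"green"` suffices for heart
#'   rate; SpO2 needs `c("red", "green")`).
#' @param hr_range,spo2_range,rr_range per-subject uniform ranges.
#' @param noise_sd generator noise scale.
#' @param filter apply [wavelet_filter()] before segmentation.
#' @param seed integer seed.
#' @return A `segment_dataset` with `subject` populated.
#' @export
gen_vitals_dataset <- function(n_subjects = 10, duration_each = 120,
                               fs = 30, w_s = 10, vitals = "hr",
                               channels = "green",
                               hr_range = c(50, 110),
                               spo2_range = c(90, 100),
                               rr_range = c(8, 25),
                               noise_sd = 0.02, filter = TRUE, seed = 1L) {
  set.seed(seed)
  params <- data.frame(
    hr = stats::runif(n_subjects, hr_range[1], hr_range[2]),
    spo2 = stats::runif(n_subjects, spo2_range[1], spo2_range[2]),
    rr = stats::runif(n_subjects, rr_range[1], rr_range[2]),
    seed = sample.int(2^30, n_subjects)
  )
  dsl <- lapply(seq_len(n_subjects), function(i) {
    cfg <- sim_config(fs = fs, duration = duration_each, hr = params$hr[i],
                      rr = params$rr[i], spo2 = params$spo2[i],
                      noise_sd = noise_sd, seed = params$seed[i])
    rec <- gen_paired_recording(cfg)
    x <- rec$ppg[, channels, drop = FALSE]
    if (filter) x <- wavelet_filter(x, wavelet_spec())
    segment_signal(x, rec$labels[, vitals, drop = FALSE], w_s = w_s,
                   subject = i)
  })
  combine_segments(dsl)
}
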