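#' P2E model specification
#'
#' Configuration of the cycle-wise PPG-to-ECG coefficient regressor. Both
#' configurations map the leading `l_p` DCT coefficients of a PPG cycle to
#' the leading `l_e` DCT coefficients of the concurrent ECG cycle: `ridge`
#' solves the penalized least-squares map in closed form, `ffnn` trains a
#' two-hidden-layer network (selu activation followed by batch
#' normalization per hidden layer, L1 weight penalty, Xavier
#' initialization, Adam under the MAE criterion with staircase exponential
#' learning-rate decay and early stopping).
#'
#' @param config `"ridge"` or `"ffnn"`.
#' @param l_p,l_e number of PPG / ECG DCT coefficients (default 150 each).
#' @param lambda ridge penalty.
#' @param hidden hidden-layer widths for the ffnn configuration.
#' @param activation hidden activation, `"selu"` (default) or `"tanh"`.
#' @param l1 L1 penalty on hidden-layer weights.
#' @param epochs,batch_size,lr,patience ffnn training controls.
#' @param lr_decay_every epochs per staircase learning-rate step (factor
#'   `exp(-0.1)`).
#' @return An object of class `p2e_spec`.
#' @export
p2e_spec <- function(config = c("ffnn", "ridge"), l_p = 150, l_e = 150,
                     lambda = 1e-3, hidden = c(175, 175),
                     activation = c("selu", "tanh"), l1 = 1e-5,
                     epochs = 1000, batch_size = 100, lr = 1e-3,
                     patience = 30, lr_decay_every = 50) {
  config <- match.arg(config)
  activation <- match.arg(activation)
  stopifnot(l_p >= 1, l_e >= 1, lambda >= 0, all(hidden > 0))
  structure(list(config = config, l_p = l_p, l_e = l_e, lambda = lambda,
                 hidden = hidden, activation = activation, l1 = l1,
                 epochs = epochs, batch_size = batch_size, lr = lr,
                 patience = patience, lr_decay_every = lr_decay_every),
            class = "p2e_spec")
}

#' Cut a detrended PPG/ECG pair into aligned cardiac cycle pairs
#'
#' Matches each ECG R-peak with the following PPG pulse peak, estimates the
#' pulse-transit lag as the median offset of the matched pairs, advances
#' the PPG by that lag, and cuts both signals into per-beat cycles at
#' successive reference points (each cycle starts a fixed fraction of the
#' median beat before its R-peak so the full P-QRS-T complex lies inside).
#' Every cycle is linearly resampled to a common length `L`; beats
#' truncated by the recording edges or without a matched pulse peak are
#' dropped.
#'
#' @param ppg,ecg detrended single-channel [ppg_signal()]s with equal
#'   sampling rates.
#' @param ppg_peaks,r_peaks pulse-peak / R-peak indices ([peak_set()] or
#'   integer vectors).
#' @param L common resampled cycle length (default 300 samples).
#' @param pre_frac fraction of the median beat placed before the R-peak
#'   (default 0.35).
#' @param max_unmatched tolerated fraction of R-peaks without a matching
#'   pulse peak before erroring.
#' @return An object of class `cycle_pairs`: list of
#'   `list(ppg, ecg, r_index, len, start)` with attributes `L`, `fs`,
#'   `lag` (samples).
#' @export
pair_cycles <- function(ppg, ecg, ppg_peaks, r_peaks, L = 300,
                        pre_frac = 0.35, max_unmatched = 0.2) {
  stopifnot(inherits(ppg, "ppg_signal"), inherits(ecg, "ppg_signal"))
  if (fs(ppg) != fs(ecg)) stop("ppg and ecg sampling rates differ", call. = FALSE)
  f <- fs(ppg)
  pv <- channel(ppg, 1)
  ev <- channel(ecg, 1)
  pk <- peak_indices(ppg_peaks)
  rk <- peak_indices(r_peaks)
  if (length(pk) < 2 || length(rk) < 2) stop("need at least 2 peaks each", call. = FALSE)
  # match each R-peak to the first pulse peak within (0, 0.6 s]
  max_lag <- round(0.6 * f)
  offsets <- rep(NA_real_, length(rk))
  for (i in seq_along(rk)) {
    cand <- pk[pk > rk[i] & pk <= rk[i] + max_lag]
    if (length(cand)) offsets[i] <- cand[1] - rk[i]
  }
  unmatched <- mean(is.na(offsets))
  if (unmatched > max_unmatched) {
    stop(sprintf("%.0f%% of R-peaks have no matching pulse peak (beats %s)",
                 100 * unmatched,
                 paste(utils::head(which(is.na(offsets)), 5), collapse = ", ")),
         call. = FALSE)
  }
  lag <- round(stats::median(offsets, na.rm = TRUE))
  period <- stats::median(diff(rk))
  s0 <- round(pre_frac * period)
  n <- length(ev)
  pairs <- list()
  for (i in seq_len(length(rk) - 1)) {
    a <- rk[i] - s0
    b <- rk[i + 1] - s0 - 1
    if (a < 1 || b > n || b + lag > length(pv)) next # truncated beat
    len <- b - a + 1
    ce <- ev[a:b]
    cp <- pv[(a + lag):(b + lag)]
    r_rel <- rk[i] - a + 1
    grid <- seq(1, len, length.out = L)
    pairs[[length(pairs) + 1]] <- list(
      ppg = stats::approx(seq_len(len), cp, xout = grid)$y,
      ecg = stats::approx(seq_len(len), ce, xout = grid)$y,
      r_index = round((r_rel - 1) * (L - 1) / (len - 1)) + 1,
      len = len, start = a
    )
  }
  structure(pairs, class = "cycle_pairs", L = L, fs = f, lag = lag)
}

#' @export
`[.cycle_pairs` <- function(x, i) {
  structure(unclass(x)[i], class = "cycle_pairs", L = attr(x, "L"),
            fs = attr(x, "fs"), lag = attr(x, "lag"))
}

#' @export
print.cycle_pairs <- function(x, ...) {
  cat(sprintf("<cycle_pairs> %d cycles, L = %d @ %g Hz, lag = %d samples\n",
              length(x), attr(x, "L"), attr(x, "fs"), attr(x, "lag")))
  invisible(x)
}

cycles_to_dct <- function(pairs, l_p, l_e) {
  L <- attr(pairs, "L")
  X <- t(vapply(pairs, function(p) dct_truncate(p$ppg, l_p), numeric(l_p)))
  Y <- t(vapply(pairs, function(p) dct_truncate(p$ecg, l_e), numeric(l_e)))
  list(X = X, Y = Y, L = L)
}

#' Fit the PPG-to-ECG coefficient regressor
#'
#' @param pairs a [pair_cycles()] result (training cycles).
#' @param spec a [p2e_spec()].
#' @param seed RNG seed for the ffnn configuration (initialization,
#'   shuffling, validation split).
#' @param verbose print training progress every this many epochs (ffnn).
#' @return An object of class `p2e_model` exposing [predict_p2e()] and
#'   [reconstruct_ecg()]; contains the fit (`W` or `net`), the training
#'   `history` (ffnn), and the centering/scaling constants.
#' @export
fit_p2e <- function(pairs, spec = p2e_spec(), seed = 1L, verbose = 0) {
  if (length(pairs) < 10) stop("need at least 10 cycle pairs", call. = FALSE)
  d <- cycles_to_dct(pairs, spec$l_p, spec$l_e)
  x_center <- colMeans(d$X)
  y_center <- colMeans(d$Y)
  Xc <- sweep(d$X, 2, x_center)
  Yc <- sweep(d$Y, 2, y_center)
  x_scale <- stats::sd(Xc)
  y_scale <- stats::sd(Yc)
  model <- list(config = spec$config, spec = spec, L = d$L,
                x_center = x_center, y_center = y_center,
                x_scale = x_scale, y_scale = y_scale)
  if (spec$config == "ridge") {
    XtX <- crossprod(Xc)
    diag(XtX) <- diag(XtX) + spec$lambda
    W <- tryCatch(
      solve(XtX, crossprod(Xc, Yc)),
      error = function(e) stop(
        "singular design matrix; increase the ridge penalty (lambda > 0)",
        call. = FALSE)
    )
    model$W <- W
  } else {
    set.seed(seed)
    net <- nn_sequential(list(
      layer_dense(spec$l_p, spec$hidden[1], l1 = spec$l1),
      layer_activation(spec$activation),
      layer_batchnorm(spec$hidden[1]),
      layer_dense(spec$hidden[1], spec$hidden[2], l1 = spec$l1),
      layer_activation(spec$activation),
      layer_batchnorm(spec$hidden[2]),
      layer_dense(spec$hidden[2], spec$l_e)
    ))
    fit <- nn_train(net, Xc / x_scale, Yc / y_scale,
                    epochs = spec$epochs, batch_size = spec$batch_size,
                    lr = spec$lr, val_frac = 0.15,
                    patience = spec$patience,
                    schedule = lr_schedule_staircase(exp(-0.1),
                                                     spec$lr_decay_every),
                    seed = seed, verbose = verbose)
    model$net <- fit$model
    model$history <- fit$history
  }
  structure(model, class = "p2e_model")
}

#' Predict ECG DCT coefficients from PPG DCT coefficients
#'
#' @param model a fitted [fit_p2e()] model.
#' @param c_p matrix `(n, l_p)` of PPG coefficients (a vector is promoted
#'   to one row).
#' @return Matrix `(n, l_e)` of predicted ECG coefficients.
#' @export
predict_p2e <- function(model, c_p) {
  if (is.null(dim(c_p))) c_p <- matrix(c_p, nrow = 1)
  Xc <- sweep(c_p, 2, model$x_center)
  if (model$config == "ridge") {
    Yc <- Xc %*% model$W
  } else {
    Yc <- nn_predict(model$net, Xc / model$x_scale) * model$y_scale
  }
  sweep(Yc, 2, model$y_center, "+")
}

#' Reconstruct one ECG cycle (fixed length) per predicted coefficient row
#'
#' @param model a `p2e_model`.
#' @param pairs cycle pairs whose PPG cycles are translated.
#' @return Matrix `(n, L)` of reconstructed ECG cycles on the detrended
#'   scale.
#' @export
translate_cycles <- function(model, pairs) {
  d <- cycles_to_dct(pairs, model$spec$l_p, model$spec$l_e)
  ce_hat <- predict_p2e(model, d$X)
  t(apply(ce_hat, 1, idct_reconstruct, n = model$L))
}

#' Synthesize a single-lead ECG from a detrended PPG alone
#'
#' Test-time translation: the PPG is cut into cycles at its pulse peaks (no
#' ECG or synchronization needed), each cycle is resampled to the model's
#' training length, its truncated DCT is mapped through the fitted
#' regressor, the predicted coefficients are inverse-transformed, and each
#' cycle is resampled back to its native beat length so the synthetic ECG
#' keeps the subject's rhythm.
#'
#' @param ppg detrended single-channel [ppg_signal()].
#' @param peaks pulse-peak indices ([peak_set()] or integer vector).
#' @param model a fitted `p2e_model`.
#' @param pre_frac cycle cut offset before each pulse peak as a fraction of
#'   the median beat (default 0.35, matching [pair_cycles()]).
#' @return List with `ecg` (single-channel [ppg_signal()] covering the
#'   spanned samples), `start` (first covered sample of the input), and
#'   `cycles` (list of native-length reconstructed cycles).
#' @export
reconstruct_ecg <- function(ppg, peaks, model, pre_frac = 0.35) {
  stopifnot(inherits(model, "p2e_model"))
  pv <- channel(ppg, 1)
  pk <- peak_indices(peaks)
  if (length(pk) < 2) stop("no detectable cycles (need >= 2 pulse peaks)", call. = FALSE)
  period <- stats::median(diff(pk))
  s0 <- round(pre_frac * period)
  L <- model$L
  out <- numeric(0)
  cycles <- list()
  start <- NA_integer_
  for (i in seq_len(length(pk) - 1)) {
    a <- pk[i] - s0
    b <- pk[i + 1] - s0 - 1
    if (a < 1 || b > length(pv)) next
    if (is.na(start)) start <- a
    len <- b - a + 1
    grid <- seq(1, len, length.out = L)
    cyc <- stats::approx(seq_len(len), pv[a:b], xout = grid)$y
    ce_hat <- predict_p2e(model, dct_truncate(cyc, model$spec$l_p))
    rec_L <- idct_reconstruct(as.numeric(ce_hat), L)
    rec <- stats::approx(seq_len(L), rec_L,
                         xout = seq(1, L, length.out = len))$y
    cycles[[length(cycles) + 1]] <- rec
    out <- c(out, rec)
  }
  if (!length(cycles)) stop("no complete cycles inside the recording", call. = FALSE)
  list(ecg = ppg_signal(out, fs = fs(ppg), channels = "ecg_synth"),
       start = start, cycles = cycles)
}

#' Cycle-level evaluation of a fitted P2E model
#'
#' Translates every PPG cycle of `pairs` and scores it against its
#' reference ECG cycle with the Pearson correlation, MAE and worst-case
#' pointwise distance.
#'
#' @param model a `p2e_model`.
#' @param pairs held-out cycle pairs.
#' @return List with `per_cycle` (data.frame: pcorr, mae, l_dir) and
#'   `summary` (means over cycles).
#' @export
p2e_evaluate <- function(model, pairs) {
  rec <- translate_cycles(model, pairs)
  ref <- t(vapply(pairs, function(p) {
    dct_ref <- dct_truncate(p$ecg, model$spec$l_e)
    idct_reconstruct(dct_ref, model$L)
  }, numeric(model$L)))
  # score against the raw reference cycle (not its truncated-DCT smoothing)
  raw <- t(vapply(pairs, `[[`, numeric(attr(pairs, "L")), "ecg"))
  per <- data.frame(
    pcorr = vapply(seq_len(nrow(rec)), function(i) pearson(raw[i, ], rec[i, ]),
                   numeric(1)),
    mae = vapply(seq_len(nrow(rec)), function(i) mean(abs(raw[i, ] - rec[i, ])),
                 numeric(1)),
    l_dir = vapply(seq_len(nrow(rec)),
                   function(i) dirichlet_distance(raw[i, ], rec[i, ]),
                   numeric(1))
  )
  list(per_cycle = per,
       summary = c(pcorr = mean(per$pcorr), mae = mean(per$mae),
                   l_dir = mean(per$l_dir)),
       reconstructed = rec, reference = raw)
}

#' Sweep the number of PPG DCT coefficients
#'
#' Refits the model for every coefficient count in `grid` (ridge by
#' default; a reduced-epoch ffnn is allowed via `spec`) and records the
#' held-out cycle-level metrics.
#'
#' @param pairs_train,pairs_test training and evaluation cycle pairs.
#' @param grid vector of coefficient counts (each within `1..L`).
#' @param spec base [p2e_spec()]; its `l_p` is replaced per grid point.
#' @param seed seed forwarded to [fit_p2e()].
#' @return data.frame with columns `l_p`, `mae`, `pcorr`, `l_dir`.
#' @export
coefficient_sweep <- function(pairs_train, pairs_test, grid,
                              spec = p2e_spec("ridge"), seed = 1L) {
  if (!length(grid)) stop("empty grid", call. = FALSE)
  L <- attr(pairs_train, "L")
  if (any(grid < 1 | grid > L)) stop("grid outside [1, L]", call. = FALSE)
  rows <- lapply(grid, function(lp) {
    sp <- spec
    sp$l_p <- lp
    m <- fit_p2e(pairs_train, sp, seed = seed)
    s <- p2e_evaluate(m, pairs_test)$summary
    data.frame(l_p = lp, mae = s[["mae"]], pcorr = s[["pcorr"]],
               l_dir = s[["l_dir"]])
  })
  do.call(rbind, rows)
}

#' Generate a preprocessed corpus of synthetic cycle pairs
#'
#' Runs the full training-side pipeline on synthetic recordings until
#' `n_pairs` aligned cycle pairs are collected: paired PPG/ECG generation
#' (heart rate and pulse-transit lag drawn per recording), wavelet
#' filtering, TERMA peak and valley detection, envelope detrending of both
#' signals, and cycle pairing.
#'
#' @param n_pairs number of cycle pairs to collect.
#' @param hr_range,ptt_range per-recording uniform ranges for heart rate
#'   (beats/min) and pulse-transit lag (ms).
#' @param noise_sd generator noise scale.
#' @param fs sampling rate, Hz.
#' @param duration_each seconds per synthetic recording.
#' @param L resampled cycle length.
#' @param seed integer seed.
#' @return A `cycle_pairs` object with exactly `n_pairs` elements (the
#'   recording index of each cycle in attribute `recording`).
#' @export
gen_cycle_pairs <- function(n_pairs, hr_range = c(55, 110),
                            ptt_range = c(150, 250), noise_sd = 0.02,
                            fs = 125, duration_each = 60, L = 300,
                            seed = 11L) {
  all_pairs <- list()
  rec_id <- integer(0)
  k <- 0
  set.seed(seed)
  while (length(all_pairs) < n_pairs && k < 1000) {
    k <- k + 1
    hr <- stats::runif(1, hr_range[1], hr_range[2])
    ptt <- stats::runif(1, ptt_range[1], ptt_range[2])
    rec_seed <- sample.int(2^30, 1)
    cfg <- sim_config(fs = fs, duration = duration_each, hr = hr,
                      ptt_lag = ptt, noise_sd = noise_sd, seed = rec_seed)
    rec <- gen_paired_recording(cfg)
    pairs <- preprocess_and_pair(rec, L = L)
    if (is.null(pairs)) next
    all_pairs <- c(all_pairs, unclass(pairs))
    rec_id <- c(rec_id, rep(k, length(pairs)))
  }
  if (length(all_pairs) < n_pairs) {
    stop("could not collect enough cycle pairs", call. = FALSE)
  }
  keep <- seq_len(n_pairs)
  structure(all_pairs[keep], class = "cycle_pairs", L = L, fs = fs,
            lag = NA_integer_, recording = rec_id[keep])
}

# wavelet filter, detect fiducials, detrend both traces and pair cycles;
# returns NULL when detection fails on a pathological draw
preprocess_and_pair <- function(rec, L = 300) {
  tryCatch({
    ppg_f <- wavelet_filter(
      ppg_signal(channel(rec$ppg, "green"), fs = fs(rec$ppg)),
      wavelet_spec()
    )
    ecg_f <- wavelet_filter(rec$ecg, wavelet_spec())
    pk_p <- terma_detect(ppg_f, terma_profile_ppg())
    pk_e <- terma_detect(ecg_f, terma_profile_ecg())
    if (nrow(pk_p) < 3 || nrow(pk_e) < 3) return(NULL)
    vl_p <- detect_valleys(ppg_f, pk_p)
    vl_e <- detect_valleys(ecg_f, pk_e)
    ppg_d <- suppressWarnings(detrend_envelope(ppg_f, pk_p, vl_p))
    ecg_d <- suppressWarnings(detrend_envelope(ecg_f, pk_e, vl_e))
    pair_cycles(ppg_d, ecg_d, pk_p, pk_e, L = L)
  }, error = function(e) NULL)
}
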