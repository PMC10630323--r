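#' Envelope detrending of a pulsatile signal
#'
#' Normalizes a PPG or ECG trace between its beat-to-beat envelopes: a
#' lower envelope is interpolated through the valleys and an upper envelope
#' through the peaks (natural cubic splines), the signal is mapped to
#' `(x - lower) / (upper - lower)` so its magnitude lies between 0 and 1,
#' and an offset of 0.5 is subtracted to centre it at zero. Peak samples
#' map to +0.5 and valley samples to -0.5. Beyond the outermost fiducials
#' the envelopes are clamped to their nearest value.
#'
#' @param x single-channel [ppg_signal()] or numeric vector.
#' @param peaks,valleys peak/valley sample indices (integer vectors or
#'   [peak_set()] objects); at least two of each.
#' @param overshoot_tol warn when spline overshoot pushes samples between
#'   the first and last fiducial beyond `0.5 + overshoot_tol` in magnitude
#'   (default 0.05).
#' @return Detrended signal of the same type as `x`, centred on zero.
#' @export
detrend_envelope <- function(x, peaks, valleys, overshoot_tol = 0.05) {
  was_signal <- inherits(x, "ppg_signal")
  if (was_signal) {
    if (ncol(x) != 1) stop("detrending expects a single channel", call. = FALSE)
    v <- channel(x, 1)
  } else {
    v <- as.numeric(x)
  }
  pk <- peak_indices(peaks)
  vl <- peak_indices(valleys)
  if (length(pk) < 2 || length(vl) < 2) {
    stop("need at least 2 peaks and 2 valleys", call. = FALSE)
  }
  n <- length(v)
  upper <- clamped_spline(pk, v[pk], n)
  lower <- clamped_spline(vl, v[vl], n)
  den <- upper - lower
  bad <- which(den <= 0)
  if (length(bad)) {
    stop("degenerate envelope (upper <= lower) first at sample ", bad[1],
         call. = FALSE)
  }
  y <- (v - lower) / den - 0.5
  lo <- min(pk[1], vl[1])
  hi <- max(pk[length(pk)], vl[length(vl)])
  inner <- y[lo:hi]
  if (any(abs(inner) > 0.5 + overshoot_tol)) {
    warning(sprintf("spline overshoot beyond +/-%.2f between fiducials",
                    0.5 + overshoot_tol))
  }
  if (was_signal) new_signal_like(x, matrix(y, ncol = 1)) else y
}

# natural cubic spline through (idx, val), evaluated at 1..n and clamped to
# the nearest fiducial value outside [min(idx), max(idx)]
clamped_spline <- function(idx, val, n) {
  e <- stats::spline(idx, val, xout = seq_len(n), method = "natural")$y
  lo <- min(idx)
  hi <- max(idx)
  if (lo > 1) e[seq_len(lo - 1)] <- e[lo]
  if (hi < n) e[(hi + 1):n] <- e[hi]
  e
}

#' Sliding-window segmentation with window-averaged labels
#'
#' Cuts a signal into fixed-width windows starting every `stride` seconds
#' and pairs each window with the arithmetic mean of the per-second vitals
#' labels it spans. For an integer-second recording of T seconds and
#' 1-second stride this yields `T - w_s + 1` windows.
#'
#' @param x a [ppg_signal()].
#' @param labels per-second label stream: data.frame with one row per
#'   second and one column per vital, or a numeric vector (single vital).
#' @param w_s window length, seconds; `w_s * fs(x)` must be integral.
#' @param stride window step, seconds (default 1).
#' @param subject optional subject identifier recorded with every segment.
#' @return An object of class `segment_dataset`: list with `segments`
#'   (array `N x (w_s * fs) x ch`), `labels` (matrix `N x N_v`), `subject`
#'   (length-N vector), and fields `w_s`, `fs`, `ch`, `vitals`.
#' @export
segment_signal <- function(x, labels, w_s, stride = 1, subject = NA) {
  stopifnot(inherits(x, "ppg_signal"))
  f <- fs(x)
  wlen <- w_s * f
  if (abs(wlen - round(wlen)) > 1e-9) {
    stop("w_s * fs must be an integral number of samples", call. = FALSE)
  }
  wlen <- as.integer(round(wlen))
  if (is.vector(labels) && is.numeric(labels)) {
    labels <- data.frame(value = labels)
  }
  labels <- labels[, setdiff(names(labels), "second"), drop = FALSE]
  T_sec <- floor(nrow(x) / f)
  if (w_s > T_sec) stop("w_s exceeds the recording duration", call. = FALSE)
  if (nrow(labels) < T_sec) {
    stop("label stream does not cover the signal duration", call. = FALSE)
  }
  starts <- seq(0, T_sec - w_s, by = stride)
  N <- length(starts)
  segs <- array(0, dim = c(N, wlen, ncol(x)))
  labs <- matrix(0, N, ncol(labels))
  colnames(labs) <- names(labels)
  for (i in seq_len(N)) {
    s0 <- round(starts[i] * f)
    segs[i, , ] <- unclass(x)[(s0 + 1):(s0 + wlen), , drop = FALSE]
    sec0 <- floor(starts[i])
    labs[i, ] <- colMeans(labels[(sec0 + 1):(sec0 + w_s), , drop = FALSE])
  }
  structure(list(
    segments = segs, labels = labs,
    subject = rep(subject, N),
    w_s = w_s, fs = f, ch = ncol(x), vitals = names(labels)
  ), class = "segment_dataset")
}

#' Concatenate segment datasets from several recordings
#'
#' @param dsl list of `segment_dataset` objects sharing `w_s`, `fs`, `ch`
#'   and vitals.
#' @return A single `segment_dataset`.
#' @export
combine_segments <- function(dsl) {
  stopifnot(length(dsl) >= 1)
  ref <- dsl[[1]]
  for (d in dsl[-1]) {
    if (d$w_s != ref$w_s || d$fs != ref$fs || d$ch != ref$ch ||
        !identical(d$vitals, ref$vitals)) {
      stop("segment datasets are not compatible", call. = FALSE)
    }
  }
  N <- sum(vapply(dsl, function(d) dim(d$segments)[1], integer(1)))
  segs <- array(0, dim = c(N, dim(ref$segments)[2], ref$ch))
  labs <- matrix(0, N, ncol(ref$labels))
  colnames(labs) <- colnames(ref$labels)
  subj <- rep(NA, N)
  at <- 0
  for (d in dsl) {
    k <- dim(d$segments)[1]
    segs[at + seq_len(k), , ] <- d$segments
    labs[at + seq_len(k), ] <- d$labels
    subj[at + seq_len(k)] <- d$subject
    at <- at + k
  }
  structure(list(segments = segs, labels = labs, subject = subj,
                 w_s = ref$w_s, fs = ref$fs, ch = ref$ch,
                 vitals = ref$vitals), class = "segment_dataset")
}

#' @export
print.segment_dataset <- function(x, ...) {
  cat(sprintf(
    "<segment_dataset> %d segments of %g s @ %g Hz, %d channel(s); vitals: %s\n",
    dim(x$segments)[1], x$w_s, x$fs, x$ch, paste(x$vitals, collapse = ", ")
  ))
  invisible(x)
}

#' Row subset of a segment dataset
#'
#' @param ds a `segment_dataset`.
#' @param i segment indices to keep.
#' @return A `segment_dataset` with the selected segments.
#' @export
subset_segments <- function(ds, i) {
  structure(list(
    segments = ds$segments[i, , , drop = FALSE],
    labels = ds$labels[i, , drop = FALSE],
    subject = ds$subject[i],
    w_s = ds$w_s, fs = ds$fs, ch = ds$ch, vitals = ds$vitals
  ), class = "segment_dataset")
}
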