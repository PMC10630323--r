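#' Detected peak/valley set
#'
#' A thin container for detected fiducial sample positions: strictly
#' increasing indices, a kind (`"peak"` or `"valley"`), and an optional
#' P/Q/R/S/T tag per index for ECG cycles.
#'
#' @param indices integer sample positions, strictly increasing.
#' @param kind `"peak"` or `"valley"`.
#' @param fiducial optional character vector of P/Q/R/S/T tags.
#' @return A data.frame of class `peak_set` with columns `index`, `kind`,
#'   `fiducial`.
#' @export
peak_set <- function(indices, kind = "peak", fiducial = NA_character_) {
  indices <- as.integer(indices)
  if (length(indices) > 1 && any(diff(indices) <= 0)) {
    stop("peak indices must be strictly increasing", call. = FALSE)
  }
  structure(
    data.frame(index = indices,
               kind = rep_len(kind, length(indices)),
               fiducial = rep_len(fiducial, length(indices))),
    class = c("peak_set", "data.frame")
  )
}

# accept a peak_set or a bare integer vector
peak_indices <- function(p) {
  if (inherits(p, "peak_set") || is.data.frame(p)) as.integer(p$index)
  else as.integer(p)
}

#' @rdname peak_set
#' @param p a `peak_set`.
#' @param path CSV file path.
#' @export
write_peaks <- function(p, path) {
  utils::write.csv(as.data.frame(p), path, row.names = FALSE)
  invisible(path)
}

#' @rdname peak_set
#' @export
read_peaks <- function(path) {
  df <- utils::read.csv(path)
  peak_set(df$index, df$kind, df$fiducial)
}

#' TERMA detection profile
#'
#' Window lengths for the two event-related moving averages: a short one
#' spanning the event of interest (QRS complex or systolic wave) and a long
#' one spanning roughly one cardiac cycle, plus the fractional offset added
#' to the cycle average when thresholding. Defaults follow the classical
#' two-moving-average detector family; all values are tunable, and
#' `offset_beta` can be adjusted per recording when an unusual morphology
#' defeats the default threshold.
#'
#' @param event_window event moving-average span, ms.
#' @param cycle_window cycle moving-average span, ms.
#' @param offset_beta fraction added to the cycle average to form the
#'   block-of-interest threshold.
#' @param min_separation minimum separation between reported peaks, ms;
#'   `NA` selects an adaptive refractory of 0.55 of the dominant beat
#'   period estimated from the energy autocorrelation (useful for PPG,
#'   where high-pass filtering can make the dicrotic wave comparable to
#'   the systolic wave).
#' @return An object of class `terma_profile`.
#' @export
terma_profile <- function(event_window = 97, cycle_window = 611,
                          offset_beta = 0.08, min_separation = 200) {
  stopifnot(event_window > 0, cycle_window > 0,
            is.na(min_separation) || min_separation > 0)
  if (event_window >= cycle_window) {
    stop("event_window must be shorter than cycle_window", call. = FALSE)
  }
  structure(list(event_window = event_window, cycle_window = cycle_window,
                 offset_beta = offset_beta, min_separation = min_separation),
            class = "terma_profile")
}

#' @rdname terma_profile
#' @export
terma_profile_ecg <- function(...) terma_profile(97, 611, 0.08, 200, ...)

#' @rdname terma_profile
#' @param ... overrides passed to `terma_profile()`.
#' @export
terma_profile_ppg <- function(...) terma_profile(111, 667, 0.08, NA, ...)

# beat period (samples) of a rectified-squared pulse train: the lowest
# spectral line of the energy within the physiological band (0.5-3.4 Hz,
# i.e. 30-204 beats/min) whose magnitude reaches 35% of the band maximum.
# The fundamental always clears that fraction while subharmonic leakage
# stays well below it, so the estimate resists both the harmonic-rich
# spectrum of narrow pulses and dicrotic-wave structure.
beat_period_samples <- function(y, f) {
  n <- length(y)
  sp <- Mod(stats::fft(y - mean(y)))[seq_len(n %/% 2)]
  freq <- (seq_len(n %/% 2) - 1) * f / n
  band <- which(freq >= 0.5 & freq <= 3.4)
  if (length(band) < 3 || max(sp[band]) == 0) return(round(0.5 * f))
  cand <- band[sp[band] >= 0.35 * max(sp[band])]
  round(f / freq[cand[1]])
}

# centred moving average with odd window, edges padded by replication
moving_average <- function(x, w) {
  w <- max(1L, as.integer(w))
  if (w %% 2 == 0) w <- w + 1L
  half <- (w - 1L) %/% 2L
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  cs <- cumsum(xp)
  (cs[(w):length(xp)] - c(0, cs[seq_len(length(xp) - w)])) / w
}

#' Two event-related moving averages (TERMA) peak detection
#'
#' Rectifies and squares the signal, computes a short (event) and a long
#' (cycle) moving average, marks blocks of interest where the event average
#' exceeds the cycle average inflated by `offset_beta`, discards blocks
#' shorter than the event window, and reports the signal argmax of each
#' surviving block (earliest index on ties). Peaks closer than
#' `min_separation` keep only the larger one.
#'
#' @param x single-channel [ppg_signal()].
#' @param profile a [terma_profile()]; use [terma_profile_ecg()] for
#'   R-peaks and [terma_profile_ppg()] for systolic pulse peaks.
#' @return A [peak_set()] of detected peaks.
#' @examples
#' cfg <- sim_config(duration = 30, hr = 75, seed = 4)
#' ecg <- gen_ecg(cfg)
#' pk <- terma_detect(ecg$signal, terma_profile_ecg())
#' @export
terma_detect <- function(x, profile = terma_profile_ecg()) {
  stopifnot(inherits(x, "ppg_signal"))
  if (ncol(x) != 1) stop("terma_detect expects a single channel", call. = FALSE)
  f <- fs(x)
  if (is.null(f)) stop("sampling rate missing", call. = FALSE)
  v <- channel(x, 1)
  n <- length(v)
  w_event <- round(profile$event_window / 1000 * f)
  w_cycle <- round(profile$cycle_window / 1000 * f)
  if (w_cycle >= n) stop("cycle window longer than signal", call. = FALSE)
  # remove the slow baseline, then rectify and square to emphasise the
  # event energy (argmax within blocks still uses the raw samples)
  base <- moving_average(v, round(1.0 * f))
  y <- pmax(v - base, 0)^2
  # numerically flat signals: rounding residue is not pulse energy
  y[y < (1e-9 * (max(abs(v)) + 1))^2] <- 0
  if (all(y == 0)) return(peak_set(integer(0)))
  ma_event <- moving_average(y, w_event)
  ma_cycle <- moving_average(y, w_cycle)
  # relative block criterion plus an absolute energy guard so noise-only
  # stretches between events cannot form blocks of interest
  thr <- ma_cycle * (1 + profile$offset_beta) + profile$offset_beta * mean(y)
  interest <- ma_event > thr & ma_cycle > 0
  if (!any(interest)) return(peak_set(integer(0)))
  r <- rle(interest)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= w_event
  idx <- integer(0)
  for (b in which(keep)) {
    seg <- starts[b]:ends[b]
    idx <- c(idx, seg[which.max(v[seg])])
  }
  # enforce the refractory separation, keeping the larger peak
  if (is.na(profile$min_separation)) {
    min_sep <- round(0.55 * beat_period_samples(y, f))
  } else {
    min_sep <- round(profile$min_separation / 1000 * f)
  }
  if (length(idx) > 1) {
    kept <- idx[1]
    for (i in idx[-1]) {
      last <- kept[length(kept)]
      if (i - last >= min_sep) {
        kept <- c(kept, i)
      } else if (v[i] > v[last]) {
        kept[length(kept)] <- i
      }
    }
    idx <- kept
  }
  # snap each surviving peak to the local signal maximum so every beat is
  # marked at a consistent landmark (e.g. the systolic wave rather than a
  # comparable dicrotic wave on high-pass-filtered PPG)
  w <- round(0.8 * min_sep)
  if (w > 0 && length(idx)) {
    idx <- vapply(idx, function(i) {
      seg <- max(1L, i - w):min(n, i + w)
      seg[which.max(v[seg])]
    }, integer(1))
    idx <- sort(unique(idx))
  }
  peak_set(idx, kind = "peak")
}

#' Valley detection between consecutive peaks
#'
#' One valley per peak pair: the signal argmin strictly between each two
#' consecutive peaks.
#'
#' @param x single-channel [ppg_signal()].
#' @param peaks a [peak_set()] (or integer vector) with at least 2 peaks.
#' @return A [peak_set()] of `length(peaks) - 1` valleys.
#' @export
detect_valleys <- function(x, peaks) {
  stopifnot(inherits(x, "ppg_signal"))
  v <- channel(x, 1)
  pk <- peak_indices(peaks)
  if (length(pk) < 2) stop("need at least 2 peaks", call. = FALSE)
  vl <- integer(length(pk) - 1)
  for (i in seq_len(length(pk) - 1)) {
    seg <- pk[i]:pk[i + 1]
    vl[i] <- seg[which.min(v[seg])]
  }
  peak_set(vl, kind = "valley")
}

#' Locate P, Q, R, S, T fiducials within one ECG cycle
#'
#' Given a cycle and its R-peak position, the remaining fiducials are
#' localized in fixed physiologic windows around R: Q is the minimum within
#' 80 ms before R, S the minimum within 80 ms after, P the maximum in the
#' 250-80 ms window before R, and T the maximum in the 80-400 ms window
#' after. A fiducial whose search window exceeds the cycle bounds is marked
#' absent.
#'
#' @param cycle numeric vector holding one ECG cycle.
#' @param r_index R-peak position within `cycle` (1-based).
#' @param fs sampling rate of the cycle, Hz.
#' @return A [peak_set()] with `fiducial` tags P, Q, R, S, T; absent
#'   fiducials are omitted. Amplitudes are attached as column `amplitude`.
#' @export
locate_pqrst <- function(cycle, r_index, fs) {
  cycle <- as.numeric(cycle)
  n <- length(cycle)
  ms <- function(x) round(x / 1000 * fs)
  windows <- list(
    P = list(lo = -ms(250), hi = -ms(80), type = "max"),
    Q = list(lo = -ms(80), hi = -1L, type = "min"),
    R = list(lo = 0L, hi = 0L, type = "max"),
    S = list(lo = 1L, hi = ms(80), type = "min"),
    T = list(lo = ms(80), hi = ms(400), type = "max")
  )
  rows <- list()
  for (nm in names(windows)) {
    w <- windows[[nm]]
    lo <- r_index + w$lo
    hi <- r_index + w$hi
    if (lo < 1 || hi > n || lo > hi) next # window exceeds cycle bounds
    seg <- lo:hi
    i <- if (w$type == "max") seg[which.max(cycle[seg])] else seg[which.min(cycle[seg])]
    rows[[nm]] <- data.frame(index = i, fiducial = nm,
                             amplitude = cycle[i])
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$index), ]
  out <- peak_set(df$index,
                  kind = ifelse(df$fiducial %in% c("Q", "S"), "valley", "peak"),
                  fiducial = df$fiducial)
  out$amplitude <- df$amplitude
  out
}

#' Heart rate from detected peak intervals
#'
#' @param peaks a [peak_set()] or integer vector of beat positions.
#' @param fs sampling rate, Hz.
#' @return Heart rate in beats/min from the median inter-beat interval.
#' @export
hr_from_peaks <- function(peaks, fs) {
  idx <- peak_indices(peaks)
  if (length(idx) < 2) stop("need at least 2 peaks", call. = FALSE)
  60 * fs / stats::median(diff(idx))
}
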