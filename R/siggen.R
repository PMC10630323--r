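#' Simulation configuration for the synthetic paired-signal generator
#'
#' Bundles the physiological and acquisition parameters for one synthetic
#' recording. The generator emulates simultaneously acquired fingertip
#' video-PPG (three colour channels) and a single-lead ECG with aligned
#' cardiac cycles: each PPG pulse peak lags its R-peak by the pulse-transit
#' lag, respiration modulates baseline and pulse amplitude at the
#' respiratory frequency, and the colour channels' AC/DC ratios encode
#' SpO2 through a fixed ratio-of-ratios convention (see
#' [spo2_from_ratio()]).
#'
#' @param fs sampling rate, Hz.
#' @param duration recording length, seconds.
#' @param hr heart rate, beats/min (30-220). A scalar; cycle lengths are
#'   additionally modulated by respiratory sinus arrhythmia (`rsa_frac`).
#' @param rr respiratory rate, breaths/min (5-60).
#' @param spo2 blood oxygen saturation, percent (70-100).
#' @param ptt_lag pulse-transit lag between an R-peak and the following PPG
#'   pulse peak, milliseconds.
#' @param noise_sd additive white-noise scale, relative to the unit R-peak
#'   for ECG and to each channel's pulsatile (AC) amplitude for PPG.
#' @param drift_amp respiratory baseline-wander amplitude, relative to the
#'   PPG AC amplitude.
#' @param rsa_frac fractional modulation of the cardiac cycle length at the
#'   respiratory frequency (respiratory sinus arrhythmia); 0 disables it.
#' @param am_frac fractional respiratory amplitude modulation of the PPG
#'   pulse.
#' @param seed integer seed; identical configurations generate bit-identical
#'   outputs.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(fs = 125, duration = 60, hr = 75, rr = 15,
                       spo2 = 98, ptt_lag = 200, noise_sd = 0.02,
                       drift_amp = 0.3, rsa_frac = 0.02, am_frac = 0.15,
                       seed = 1L) {
  stopifnot(fs > 0, duration > 0)
  if (hr < 30 || hr > 220) stop("hr outside physiological range 30-220 beats/min", call. = FALSE)
  if (rr < 5 || rr > 60) stop("rr outside physiological range 5-60 breaths/min", call. = FALSE)
  if (spo2 < 70 || spo2 > 100) stop("spo2 outside range 70-100%", call. = FALSE)
  structure(list(
    fs = fs, duration = duration, hr = hr, rr = rr, spo2 = spo2,
    ptt_lag = ptt_lag, noise_sd = noise_sd, drift_amp = drift_amp,
    rsa_frac = rsa_frac, am_frac = am_frac, seed = as.integer(seed)
  ), class = "sim_config")
}

# evaluate code under a local RNG state so generators are reproducible
# without disturbing the caller's random stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# classical five-Gaussian ECG morphology: angular positions (rad),
# amplitudes scaled to a unit R-peak, and angular widths for P,Q,R,S,T
ecg_morphology_default <- function() {
  list(
    theta = c(P = -70, Q = -15, R = 0, S = 15, T = 100) * pi / 180,
    amp   = c(P = 1.2, Q = -5, R = 30, S = -7.5, T = 0.75) / 30,
    width = c(P = 0.25, Q = 0.1, R = 0.1, S = 0.1, T = 0.4)
  )
}

# R-peak times on the sample grid: cycle lengths follow hr with
# respiratory-sinus modulation at the rr frequency
r_peak_times <- function(cfg) {
  mean_period <- 60 / cfg$hr
  times <- numeric(0)
  t_k <- 0.5 * mean_period
  while (t_k < cfg$duration - 0.6 * mean_period) {
    # snap each R-peak to the sample grid so truth indices are exact
    t_k <- round(t_k * cfg$fs) / cfg$fs
    times <- c(times, t_k)
    period <- mean_period *
      (1 + cfg$rsa_frac * sin(2 * pi * cfg$rr / 60 * t_k))
    t_k <- t_k + period
  }
  times
}

#' Generate a synthetic single-lead ECG with known R-peak positions
#'
#' Builds a quasi-periodic waveform cycle by cycle from five Gaussian bumps
#' (P, Q, R, S, T) at configurable phase offsets; the instantaneous cycle
#' length follows `cfg$hr` with respiratory-sinus modulation at `cfg$rr`.
#'
#' @param cfg a [sim_config()].
#' @param morphology list with `theta`, `amp`, `width` vectors for the five
#'   fiducials; defaults to the classical parameterization.
#' @return List with `signal` (single-channel [ppg_signal()], unit R-peak
#'   amplitude before noise), `r_peaks` (exact R-peak sample indices,
#'   1-based), and `r_times` (seconds).
#' @export
gen_ecg <- function(cfg, morphology = ecg_morphology_default()) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    n <- round(cfg$duration * cfg$fs)
    t <- (seq_len(n) - 1) / cfg$fs
    r_times <- r_peak_times(cfg)
    x <- numeric(n)
    periods <- diff(c(r_times, r_times[length(r_times)] +
                        60 / cfg$hr))
    for (k in seq_along(r_times)) {
      t_k <- r_times[k]
      T_k <- periods[k]
      lo <- max(1L, floor((t_k - 0.6 * T_k) * cfg$fs) + 1L)
      hi <- min(n, ceiling((t_k + 0.8 * T_k) * cfg$fs) + 1L)
      idx <- lo:hi
      theta <- 2 * pi * (t[idx] - t_k) / T_k
      for (j in seq_along(morphology$theta)) {
        x[idx] <- x[idx] + morphology$amp[j] *
          exp(-(theta - morphology$theta[j])^2 / (2 * morphology$width[j]^2))
      }
    }
    if (cfg$noise_sd > 0) x <- x + stats::rnorm(n, 0, cfg$noise_sd)
    r_idx <- round(r_times * cfg$fs) + 1L
    list(
      signal = ppg_signal(x, fs = cfg$fs, channels = "ecg"),
      r_peaks = r_idx,
      r_times = r_times
    )
  })
}

#' Generate a three-channel synthetic PPG aligned to ECG R-peaks
#'
#' Each cardiac cycle carries a systolic Gaussian wave delayed by the
#' pulse-transit lag from the R-peak plus a smaller dicrotic wave. The
#' channel AC/DC amplitude ratios are set so that the red/green
#' ratio-of-ratios maps affinely to `cfg$spo2` (SpO2 = 110 - 25 R);
#' respiration adds baseline drift and amplitude modulation at the
#' respiratory frequency.
#'
#' @param cfg a [sim_config()].
#' @param r_peaks R-peak sample indices from [gen_ecg()].
#' @return List with `signal` (3-channel [ppg_signal()], red/green/blue on
#'   an 8-bit-like intensity scale), `pulse_peaks` (systolic-peak sample
#'   indices), and `ac`, `dc` (per-channel amplitudes used).
#' @export
gen_ppg <- function(cfg, r_peaks) {
  stopifnot(inherits(cfg, "sim_config"))
  if (length(r_peaks) < 2) stop("missing R-peaks: need at least 2", call. = FALSE)
  with_seed(cfg$seed + 1L, {
    n <- round(cfg$duration * cfg$fs)
    t <- (seq_len(n) - 1) / cfg$fs
    lag <- round(cfg$ptt_lag / 1000 * cfg$fs)
    pulse_idx <- r_peaks + lag
    pulse_idx <- pulse_idx[pulse_idx <= n]
    # unit-amplitude pulsatile waveform shared by all channels
    shape <- numeric(n)
    periods <- diff(c(pulse_idx, pulse_idx[length(pulse_idx)] +
                        round(60 / cfg$hr * cfg$fs))) / cfg$fs
    for (k in seq_along(pulse_idx)) {
      t_k <- (pulse_idx[k] - 1) / cfg$fs
      T_k <- periods[k]
      lo <- max(1L, floor((t_k - 0.7 * T_k) * cfg$fs) + 1L)
      hi <- min(n, ceiling((t_k + 0.9 * T_k) * cfg$fs) + 1L)
      idx <- lo:hi
      u <- (t[idx] - t_k) / T_k
      shape[idx] <- shape[idx] +
        exp(-u^2 / (2 * 0.13^2)) +          # systolic wave
        0.35 * exp(-(u - 0.35)^2 / (2 * 0.10^2)) # dicrotic wave
    }
    dc <- c(red = 150, green = 120, blue = 110)
    ratio <- ratio_for_spo2(cfg$spo2)
    ac_green <- 10
    ac <- c(
      red = ratio * ac_green * dc[["red"]] / dc[["green"]],
      green = ac_green,
      blue = 6
    )
    resp_phase <- 2 * pi * cfg$rr / 60 * t
    am <- 1 + cfg$am_frac * sin(resp_phase)
    drift <- sin(resp_phase)
    x <- matrix(0, n, 3)
    for (c in 1:3) {
      x[, c] <- dc[c] + ac[c] * (am * shape + cfg$drift_amp * drift) +
        if (cfg$noise_sd > 0) stats::rnorm(n, 0, cfg$noise_sd * ac[c]) else 0
    }
    list(
      signal = ppg_signal(x, fs = cfg$fs, channels = c("red", "green", "blue")),
      pulse_peaks = pulse_idx,
      ac = ac, dc = dc
    )
  })
}

#' SpO2 / ratio-of-ratios convention used by the generator
#'
#' The generator fixes the classical affine pulse-oximetry calibration
#' SpO2 = 110 - 25 R, where R is the red/green ratio-of-ratios
#' (AC/DC)_red / (AC/DC)_green. `ratio_for_spo2()` inverts it to set the
#' channel AC amplitudes; `spo2_from_ratio()` maps a measured R back to
#' SpO2.
#'
#' @param spo2 saturation in percent.
#' @param ratio ratio-of-ratios statistic.
#' @return The corresponding ratio or SpO2 value.
#' @export
ratio_for_spo2 <- function(spo2) (110 - spo2) / 25

#' @rdname ratio_for_spo2
#' @export
spo2_from_ratio <- function(ratio) 110 - 25 * ratio

#' Generate a full synthetic paired recording with 1 Hz labels
#'
#' Convenience wrapper producing the paired PPG/ECG recording the training
#' code consumes: both signals, exact truth peak indices, and per-second
#' label streams (HR from the generated R-R intervals, constant SpO2 and
#' RR).
#'
#' @param cfg a [sim_config()].
#' @return A list of class `paired_recording` with elements `ppg`, `ecg`
#'   (signals), `r_peaks`, `pulse_peaks`, `labels` (data.frame: second, hr,
#'   spo2, rr) and `cfg`.
#' @export
gen_paired_recording <- function(cfg) {
  ecg <- gen_ecg(cfg)
  ppg <- gen_ppg(cfg, ecg$r_peaks)
  secs <- seq_len(floor(cfg$duration))
  rt <- ecg$r_times
  inst_hr <- 60 / diff(rt)
  mid <- (rt[-1] + rt[-length(rt)]) / 2
  hr_1hz <- stats::approx(mid, inst_hr, xout = secs - 0.5, rule = 2)$y
  labels <- data.frame(
    second = secs,
    hr = hr_1hz,
    spo2 = rep(cfg$spo2, length(secs)),
    rr = rep(cfg$rr, length(secs))
  )
  structure(list(
    ppg = ppg$signal, ecg = ecg$signal,
    r_peaks = ecg$r_peaks, pulse_peaks = ppg$pulse_peaks,
    labels = labels, cfg = cfg
  ), class = "paired_recording")
}

#' Render a PPG as a stack of noisy video frames
#'
#' Each frame's pixels equal the channel value at that sample plus zero-mean
#' spatial noise, optionally quantized to 8-bit integers, so that spatial
#' averaging over any centred region recovers the PPG up to quantization.
#'
#' @param ppg a [ppg_signal()] with 1 or 3 channels, on an intensity scale
#'   within 0-255.
#' @param height,width frame dimensions in pixels.
#' @param spatial_sd standard deviation of per-pixel noise (intensity
#'   units).
#' @param quantize round to 8-bit integers and clamp to 0-255 (with a
#'   warning if clamping occurs). Set `FALSE` for float fixtures.
#' @param seed integer seed for the spatial noise.
#' @return A [frame_stack()] with `fps = fs(ppg)`.
#' @export
gen_frames <- function(ppg, height = 30, width = 30, spatial_sd = 2,
                       quantize = TRUE, seed = 1L) {
  stopifnot(inherits(ppg, "ppg_signal"))
  nch <- ncol(ppg)
  if (!nch %in% c(1L, 3L)) stop("ppg must have 1 or 3 channels", call. = FALSE)
  n <- nrow(ppg)
  with_seed(seed, {
    frames <- array(0, dim = c(height, width, nch, n))
    npix <- height * width
    vals <- unclass(ppg)
    for (tt in seq_len(n)) {
      for (c in seq_len(nch)) {
        v <- vals[tt, c] +
          if (spatial_sd > 0) stats::rnorm(npix, 0, spatial_sd) else 0
        frames[, , c, tt] <- v
      }
    }
    if (quantize) {
      if (any(frames < 0) || any(frames > 255)) {
        warning("pixel intensities clamped to [0, 255]")
        frames[frames < 0] <- 0
        frames[frames > 255] <- 255
      }
      frames <- round(frames)
    }
    frame_stack(frames, fps = fs(ppg))
  })
}

#' Generate a corpus of (PPG segment, caption, labels) records
#'
#' Draws vitals uniformly from the given ranges, synthesizes a PPG segment
#' per record (green channel, z-scored over the segment), and pairs it with
#' a templated caption built from the true vitals via [make_caption()].
#' When `include_bp = TRUE` captions additionally carry synthetic
#' systolic/diastolic blood-pressure fields (mimicking corpora whose
#' captions list SBP/DBP); parsers asked only for HR/SpO2/RR ignore them.
#'
#' @param n number of records.
#' @param hr_range,spo2_range,rr_range uniform sampling ranges for the
#'   vitals.
#' @param w_s segment length, seconds.
#' @param fs sampling rate, Hz.
#' @param include_bp add SBP/DBP fields to a random half of the captions.
#' @param seed integer seed.
#' @return A list of records, each `list(segment, caption, labels)`.
#' @export
gen_caption_corpus <- function(n, hr_range = c(50, 150),
                               spo2_range = c(90, 100),
                               rr_range = c(8, 25),
                               w_s = 10, fs = 125,
                               include_bp = FALSE, seed = 1L) {
  stopifnot(n > 0)
  with_seed(seed, {
    params <- data.frame(
      hr = round(stats::runif(n, hr_range[1], hr_range[2])),
      spo2 = round(stats::runif(n, spo2_range[1], spo2_range[2])),
      rr = round(stats::runif(n, rr_range[1], rr_range[2])),
      bp = include_bp & (stats::runif(n) < 0.5),
      seed = sample.int(2^30, n)
    )
    lapply(seq_len(n), function(i) {
      cfg <- sim_config(
        fs = fs, duration = w_s + 2, hr = params$hr[i], rr = params$rr[i],
        spo2 = params$spo2[i], seed = params$seed[i]
      )
      rec <- gen_ppg(cfg, gen_ecg(cfg)$r_peaks)
      seg <- channel(rec$signal, "green")[seq_len(w_s * fs)]
      seg <- (seg - mean(seg)) / stats::sd(seg)
      labels <- list(hr = params$hr[i], spo2 = params$spo2[i],
                     rr = params$rr[i])
      if (params$bp[i]) {
        labels$sbp <- round(100 + 0.3 * params$hr[i])
        labels$dbp <- round(65 + 0.15 * params$hr[i])
      }
      list(segment = seg, caption = make_caption(labels), labels = labels)
    })
  })
}
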