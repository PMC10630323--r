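# Orthonormal type-II DCT and a short-time Fourier transform front-end.
# DCT matrices are cached per length; cycles here are short (hundreds of
# samples) so an explicit matrix product is both exact and fast.

dct_cache <- new.env(parent = emptyenv())

#' Orthonormal type-II DCT matrix
#'
#' Row k (0-based) is `sqrt(2/N) * cos(pi * (n + 0.5) * k / N)` with the
#' first row scaled by `1/sqrt(2)`, so the matrix is orthogonal:
#' `t(C) %*% C = I`.
#'
#' @param n transform length.
#' @return `n x n` orthogonal matrix.
#' @export
dct_matrix <- function(n) {
  key <- as.character(n)
  if (!is.null(dct_cache[[key]])) return(dct_cache[[key]])
  k <- 0:(n - 1)
  m <- sqrt(2 / n) * cos(pi * outer(k, k + 0.5) / n)
  m[1, ] <- m[1, ] / sqrt(2)
  dct_cache[[key]] <- m
  m
}

#' Truncated orthonormal DCT of a cycle and its inverse
#'
#' `dct_truncate()` keeps the first `l_keep` type-II DCT coefficients of a
#' vector; `idct_reconstruct()` zero-pads a coefficient vector to length
#' `n` and inverse-transforms. At `l_keep = n` the round trip is exact;
#' truncation discards only the highest-order cosine terms, so smooth
#' cardiac cycles are represented compactly.
#'
#' @param x numeric vector (one cycle).
#' @param l_keep number of leading coefficients kept (`1..length(x)`).
#' @param coeffs truncated coefficient vector.
#' @param n reconstruction length.
#' @return `dct_truncate()`: length-`l_keep` coefficients;
#'   `idct_reconstruct()`: length-`n` signal.
#' @export
dct_truncate <- function(x, l_keep) {
  n <- length(x)
  if (l_keep < 1 || l_keep > n) stop("l_keep out of range", call. = FALSE)
  as.numeric(dct_matrix(n)[seq_len(l_keep), , drop = FALSE] %*% x)
}

#' @rdname dct_truncate
#' @export
idct_reconstruct <- function(coeffs, n) {
  if (length(coeffs) > n) stop("more coefficients than samples", call. = FALSE)
  full <- c(coeffs, numeric(n - length(coeffs)))
  as.numeric(crossprod(dct_matrix(n), full))
}

#' Short-time Fourier transform magnitude
#'
#' Frames the signal with a Hamming window and returns the one-sided FFT
#' magnitude per frame; the classic 2-D front-end that turns a PPG segment
#' into a time-frequency image.
#'
#' @param x numeric vector.
#' @param fs sampling rate, Hz.
#' @param window window length in samples.
#' @param hop hop between frame starts in samples.
#' @return Matrix `frames x bins` with attributes `freq` (Hz per bin) and
#'   `times` (frame-centre seconds).
#' @export
stft_mag <- function(x, fs, window = 128, hop = window %/% 2) {
  n <- length(x)
  if (window > n) stop("stft window longer than the signal", call. = FALSE)
  w <- 0.54 - 0.46 * cos(2 * pi * seq_len(window) / (window - 1))
  starts <- seq(1, n - window + 1, by = hop)
  nbins <- window %/% 2 + 1
  out <- matrix(0, length(starts), nbins)
  for (i in seq_along(starts)) {
    seg <- x[starts[i]:(starts[i] + window - 1)] * w
    sp <- stats::fft(seg)
    out[i, ] <- Mod(sp[seq_len(nbins)])
  }
  attr(out, "freq") <- (seq_len(nbins) - 1) * fs / window
  attr(out, "times") <- (starts - 1 + window / 2) / fs
  out
}
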