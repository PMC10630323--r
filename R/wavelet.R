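#' Wavelet filtering specification
#'
#' Parameters of the multiresolution denoising rule applied to raw PPG/ECG:
#' decompose to `levels` levels with an orthogonal wavelet, zero the
#' approximation band (slow baseline wander from respiration and ambient
#' light) and the first `drop_detail_levels` detail bands (high-frequency
#' noise and motion artifacts), and reconstruct.
#'
#' @param family wavelet family: `"db4"` (default), `"db2"` or `"haar"`.
#' @param levels decomposition depth (default 5).
#' @param drop_approx zero the deepest approximation band (default `TRUE`).
#' @param drop_detail_levels detail levels to zero, level 1 being the
#'   finest (default `c(1, 2)`).
#' @return An object of class `wavelet_spec`.
#' @export
wavelet_spec <- function(family = "db4", levels = 5, drop_approx = TRUE,
                         drop_detail_levels = c(1, 2)) {
  stopifnot(levels >= 1)
  if (length(drop_detail_levels) && max(drop_detail_levels) > levels) {
    stop("drop_detail_levels exceed decomposition depth", call. = FALSE)
  }
  wt_filters(family) # validates the family name
  structure(list(family = family, levels = as.integer(levels),
                 drop_approx = isTRUE(drop_approx),
                 drop_detail_levels = as.integer(drop_detail_levels)),
            class = "wavelet_spec")
}

# orthonormal scaling filters (reconstruction low-pass h); the analysis and
# synthesis banks are derived from h by the standard quadrature relations
wt_filters <- function(family) {
  h <- switch(family,
    haar = ,
    db1 = c(1, 1) / sqrt(2),
    db2 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2)),
    db4 = c(0.230377813308855230, 0.714846570552541500,
            0.630880767929590400, -0.027983769416983850,
            -0.187034811718881140, 0.030841381835986965,
            0.032883011666982945, -0.010597401784997278),
    stop("unknown wavelet family: ", family, call. = FALSE)
  )
  g <- rev(h) * (-1)^(seq_along(h) - 1)
  list(dec_lo = rev(h), dec_hi = rev(g), rec_lo = h, rec_hi = g)
}

# one periodized analysis step; length(x) must be even.
# a_i = sum_j dec[j] x[(2(i-1)+j-1) mod n + 1]; the synthesis below is the
# exact adjoint, so the round trip is perfect for orthonormal filters.
dwt_step <- function(x, f) {
  n <- length(x)
  n2 <- n %/% 2
  a <- numeric(n2)
  d <- numeric(n2)
  base <- 2 * (seq_len(n2) - 1)
  for (j in seq_along(f$dec_lo)) {
    p <- (base + j - 1) %% n + 1
    a <- a + f$dec_lo[j] * x[p]
    d <- d + f$dec_hi[j] * x[p]
  }
  list(a = a, d = d)
}

idwt_step <- function(a, d, f) {
  n2 <- length(a)
  n <- 2 * n2
  x <- numeric(n)
  base <- 2 * (seq_len(n2) - 1)
  for (j in seq_along(f$dec_lo)) {
    p <- (base + j - 1) %% n + 1
    x[p] <- x[p] + f$dec_lo[j] * a + f$dec_hi[j] * d
  }
  x
}

# pad a vector symmetrically on the right to a multiple of 2^levels
wt_pad <- function(x, levels) {
  m <- 2^levels
  n <- length(x)
  if (n < m) stop("signal too short for ", levels, "-level decomposition",
                  call. = FALSE)
  pad <- (m - n %% m) %% m
  if (pad > 0) x <- c(x, x[n:(n - pad + 1)])
  list(x = x, n = n)
}

#' Multilevel wavelet decomposition and reconstruction
#'
#' `dwt_decompose()` runs the fast wavelet transform to `levels` levels
#' using periodized filtering (the signal is first extended symmetrically
#' to a multiple of `2^levels`). `dwt_reconstruct()` inverts it exactly.
#'
#' @param x numeric vector.
#' @param levels decomposition depth.
#' @param family wavelet family (see [wavelet_spec()]).
#' @param coeffs a decomposition as returned by `dwt_decompose()`.
#' @return `dwt_decompose()`: list with `approx` (deepest approximation
#'   coefficients), `details` (list, element i = level-i detail
#'   coefficients, level 1 finest), and bookkeeping fields.
#'   `dwt_reconstruct()`: numeric vector of the original length.
#' @export
dwt_decompose <- function(x, levels = 5, family = "db4") {
  f <- wt_filters(family)
  p <- wt_pad(x, levels)
  a <- p$x
  details <- vector("list", levels)
  for (l in seq_len(levels)) {
    s <- dwt_step(a, f)
    details[[l]] <- s$d
    a <- s$a
  }
  list(approx = a, details = details, levels = levels, family = family,
       n = p$n)
}

#' @rdname dwt_decompose
#' @export
dwt_reconstruct <- function(coeffs) {
  f <- wt_filters(coeffs$family)
  a <- coeffs$approx
  for (l in rev(seq_len(coeffs$levels))) {
    a <- idwt_step(a, coeffs$details[[l]], f)
  }
  a[seq_len(coeffs$n)]
}

#' Wavelet denoising of a PPG/ECG signal
#'
#' Applies the band-selection rule of [wavelet_spec()] to every channel:
#' the approximation band carries the respiratory / ambient-light baseline
#' and the finest detail levels carry high-frequency noise and motion
#' artifacts, so both are zeroed before reconstruction. Output length
#' equals input length and the operation is linear in the input.
#'
#' @param x a [ppg_signal()] (any number of channels) or numeric vector.
#' @param spec a [wavelet_spec()].
#' @return Filtered signal of the same type and length as `x`.
#' @examples
#' cfg <- sim_config(duration = 20, seed = 2)
#' rec <- gen_ppg(cfg, gen_ecg(cfg)$r_peaks)
#' filt <- wavelet_filter(rec$signal, wavelet_spec())
#' @export
wavelet_filter <- function(x, spec = wavelet_spec()) {
  filt1 <- function(v) {
    if (!all(is.finite(v))) stop("non-finite samples", call. = FALSE)
    co <- dwt_decompose(v, spec$levels, spec$family)
    if (spec$drop_approx) co$approx[] <- 0
    for (l in spec$drop_detail_levels) co$details[[l]][] <- 0
    dwt_reconstruct(co)
  }
  if (inherits(x, "ppg_signal")) {
    out <- apply(unclass(x), 2, filt1)
    new_signal_like(x, out)
  } else {
    filt1(as.numeric(x))
  }
}

#' Per-band reconstructions of a signal
#'
#' Reconstructs each wavelet band in isolation (all other coefficients
#' zeroed) and returns them as columns; their row sums equal the original
#' signal. Useful for inspecting which band carries baseline wander versus
#' pulsatile energy.
#'
#' @param x numeric vector.
#' @param spec a [wavelet_spec()].
#' @return Matrix `length(x) x (levels + 1)` with columns `approx`,
#'   `d<levels>`, ..., `d1`.
#' @export
wavelet_bands <- function(x, spec = wavelet_spec()) {
  x <- as.numeric(x)
  co <- dwt_decompose(x, spec$levels, spec$family)
  zero <- function() {
    z <- co
    z$approx[] <- 0
    for (l in seq_len(z$levels)) z$details[[l]][] <- 0
    z
  }
  bands <- matrix(0, length(x), spec$levels + 1)
  colnames(bands) <- c("approx", paste0("d", rev(seq_len(spec$levels))))
  z <- zero(); z$approx <- co$approx
  bands[, 1] <- dwt_reconstruct(z)
  for (k in seq_len(spec$levels)) {
    l <- spec$levels + 1 - k # column order d<levels>..d1
    z <- zero(); z$details[[l]] <- co$details[[l]]
    bands[, k + 1] <- dwt_reconstruct(z)
  }
  bands
}
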