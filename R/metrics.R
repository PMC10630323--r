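#' Pearson correlation between two waveforms
#'
#' The centred dot product over the product of centred norms; the primary
#' morphology-similarity score between a reconstructed and a reference ECG
#' cycle.
#'
#' @param x,y equal-length numeric vectors; both must be non-constant.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 2) stop("need at least 2 samples", call. = FALSE)
  xc <- x - mean(x)
  yc <- y - mean(y)
  nx <- sqrt(sum(xc^2))
  ny <- sqrt(sum(yc^2))
  if (nx == 0 || ny == 0) stop("correlation undefined for constant input", call. = FALSE)
  sum(xc * yc) / (nx * ny)
}

#' Worst-case pointwise distance between two waveforms
#'
#' The maximum over samples of the Euclidean distance between
#' corresponding points, `max_i |x_i - y_i|`; a worst-case companion to
#' the average-case MAE. (The definition's outer minimum over the single
#' index set `[1, N]` is vacuous and implemented as the identity.)
#'
#' @param x,y equal-length numeric vectors.
#' @return Non-negative scalar.
#' @export
dirichlet_distance <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  max(abs(x - y))
}

#' Mean and standard deviation of absolute error
#'
#' `MAE` is the mean of `|y_true - y_pred|`; `SAE` is the population
#' (divide-by-N) standard deviation of the absolute errors.
#'
#' @param y_true,y_pred equal-length numeric vectors.
#' @param ddof degrees-of-freedom correction for SAE: 0 (population,
#'   default) or 1 (sample).
#' @return Named numeric vector `c(mae = , sae = )`.
#' @export
mae_sae <- function(y_true, y_pred, ddof = 0) {
  if (length(y_true) != length(y_pred)) stop("length mismatch", call. = FALSE)
  if (length(y_true) == 0) stop("empty input", call. = FALSE)
  ae <- abs(y_true - y_pred)
  m <- mean(ae)
  n <- length(ae)
  s <- if (n > ddof) sqrt(sum((ae - m)^2) / (n - ddof)) else 0
  c(mae = m, sae = s)
}

#' Per-fiducial amplitude-error table across subjects
#'
#' For every subject's (reference, reconstruction) cycle pairs, the P, Q,
#' R, S and T fiducials are located on the reference cycle and the absolute
#' amplitude difference between the two waveforms is taken at each
#' reference-fiducial sample index. Per-subject means are then summarized
#' across subjects as MMAE (mean) and MSAE (standard deviation across
#' subjects, population convention).
#'
#' @param pairs_by_subject list (one element per subject) of lists of
#'   `list(reference = , reconstruction = , r_index = )` cycle pairs;
#'   `r_index` is the R-peak position within the reference cycle.
#' @param fs sampling rate of the cycles, Hz.
#' @param redetect locate fiducials on the reconstruction rather than
#'   reusing the reference indices (default `FALSE`).
#' @return data.frame with columns `fiducial`, `mmae`, `msae`, `n_cycles`
#'   (cycles contributing across subjects; cycles whose window misses a
#'   fiducial are skipped for that fiducial).
#' @export
peak_error_table <- function(pairs_by_subject, fs, redetect = FALSE) {
  stopifnot(length(pairs_by_subject) >= 1)
  fids <- c("P", "Q", "R", "S", "T")
  per_subject <- matrix(NA_real_, length(pairs_by_subject), length(fids),
                        dimnames = list(NULL, fids))
  n_cycles <- stats::setNames(numeric(length(fids)), fids)
  for (s in seq_along(pairs_by_subject)) {
    errs <- stats::setNames(rep(list(numeric(0)), length(fids)), fids)
    for (pair in pairs_by_subject[[s]]) {
      ref_f <- locate_pqrst(pair$reference, pair$r_index, fs)
      rec_f <- if (redetect) locate_pqrst(pair$reconstruction, pair$r_index, fs)
      for (i in seq_len(nrow(ref_f))) {
        fd <- ref_f$fiducial[i]
        idx <- ref_f$index[i]
        amp_rec <- if (redetect) {
          j <- match(fd, rec_f$fiducial)
          if (is.na(j)) next
          rec_f$amplitude[j]
        } else {
          pair$reconstruction[idx]
        }
        errs[[fd]] <- c(errs[[fd]], abs(ref_f$amplitude[i] - amp_rec))
      }
    }
    for (fd in fids) {
      if (length(errs[[fd]])) {
        per_subject[s, fd] <- mean(errs[[fd]])
        n_cycles[fd] <- n_cycles[fd] + length(errs[[fd]])
      }
    }
  }
  if (length(pairs_by_subject) == 1) {
    warning("single subject: MSAE is 0 by definition")
  }
  mmae <- colMeans(per_subject, na.rm = TRUE)
  msae <- apply(per_subject, 2, function(v) {
    v <- v[!is.na(v)]
    if (length(v) <= 1) 0 else sqrt(sum((v - mean(v))^2) / length(v))
  })
  data.frame(fiducial = fids, mmae = as.numeric(mmae),
             msae = as.numeric(msae), n_cycles = as.numeric(n_cycles))
}
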