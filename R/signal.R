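#' Uniformly sampled multichannel signal
#'
#' The common currency of the pipeline: a numeric matrix with one column per
#' channel (e.g. the red/green/blue pixel-average traces of a fingertip
#' video, or a single ECG lead) together with its sampling rate.
#'
#' @param x numeric vector (single channel) or matrix with one column per
#'   channel.
#' @param fs sampling rate in Hz; must be a single positive number.
#' @param channels optional character vector of channel names; defaults to
#'   existing column names or `"ch1"`, `"ch2"`, ...
#' @return An object of class `ppg_signal`: a numeric matrix with
#'   attributes `fs` (Hz) and column names naming the channels.
#' @examples
#' s <- ppg_signal(sin(2 * pi * 1.2 * seq(0, 10, by = 1 / 125)), fs = 125)
#' fs(s)
#' n_samples(s)
#' @export
ppg_signal <- function(x, fs, channels = NULL) {
  if (is.vector(x) && is.numeric(x)) x <- matrix(x, ncol = 1)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("`x` must be a numeric vector or matrix", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  }
  if (is.null(channels)) {
    channels <- colnames(x)
    if (is.null(channels)) channels <- paste0("ch", seq_len(ncol(x)))
  }
  if (length(channels) != ncol(x)) {
    stop("length(channels) must equal ncol(x)", call. = FALSE)
  }
  colnames(x) <- channels
  structure(x, fs = as.numeric(fs), class = c("ppg_signal", "matrix", "array"))
}

#' @rdname ppg_signal
#' @param s a `ppg_signal`.
#' @export
fs <- function(s) attr(s, "fs")

#' @rdname ppg_signal
#' @export
n_samples <- function(s) nrow(s)

#' @rdname ppg_signal
#' @export
n_channels <- function(s) ncol(s)

#' @rdname ppg_signal
#' @export
duration <- function(s) nrow(s) / attr(s, "fs")

#' Extract one channel of a signal as a plain numeric vector
#'
#' @param s a `ppg_signal`.
#' @param channel column index or channel name (default first channel).
#' @return Numeric vector of samples.
#' @export
channel <- function(s, channel = 1L) {
  as.numeric(s[, channel])
}

#' @export
print.ppg_signal <- function(x, ...) {
  cat(sprintf(
    "<ppg_signal> %d samples x %d channel(s) @ %g Hz (%.2f s)\n",
    nrow(x), ncol(x), attr(x, "fs"), nrow(x) / attr(x, "fs")
  ))
  cat("channels:", paste(colnames(x), collapse = ", "), "\n")
  invisible(x)
}

# keep class + fs when subsetting rows with all columns
#' @export
`[.ppg_signal` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    attr(out, "fs") <- attr(x, "fs")
    class(out) <- class(x)
  }
  out
}

new_signal_like <- function(template, data) {
  ppg_signal(data, fs = attr(template, "fs"), channels = colnames(template))
}

#' Write / read a signal as columnar text with a sampling-rate sidecar
#'
#' `write_signal()` stores a CSV with a `time` column plus one column per
#' channel, and a JSON sidecar `<path>.json` holding `{"fs": <Hz>}`.
#' `read_signal()` reverses this; the round trip is exact to within 1e-9.
#'
#' @param s a `ppg_signal`.
#' @param path CSV file path.
#' @return `read_signal()` returns a `ppg_signal`; `write_signal()` returns
#'   `path` invisibly.
#' @export
write_signal <- function(s, path) {
  stopifnot(inherits(s, "ppg_signal"))
  t <- (seq_len(nrow(s)) - 1) / fs(s)
  df <- data.frame(time = t, unclass(s)[, , drop = FALSE], check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(fs = fs(s)), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_signal
#' @export
read_signal <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    stop("missing sampling-rate sidecar: ", sidecar, call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$fs)) stop("sidecar lacks an `fs` field", call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time" %in% names(df)) stop("malformed header: no `time` column", call. = FALSE)
  if (anyNA(df)) stop("missing values in signal file", call. = FALSE)
  t <- df$time
  if (length(t) > 1) {
    dt <- diff(t)
    if (max(abs(dt - 1 / meta$fs)) > 1e-6) {
      stop("non-uniform time column (does not match sidecar fs)", call. = FALSE)
    }
  }
  x <- as.matrix(df[setdiff(names(df), "time")])
  ppg_signal(x, fs = meta$fs)
}
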