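#' Frame stack container
#'
#' Holds a fingertip-video clip as an array of per-frame pixel intensities
#' plus the frame rate. Frames are `height x width x channels x n_frames`,
#' channel order red, green, blue.
#'
#' @param frames numeric array `H x W x C x N` (C = 1 or 3).
#' @param fps frames per second.
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, fps) {
  if (length(dim(frames)) == 3L) dim(frames) <- c(dim(frames), 1L)
  if (length(dim(frames)) != 4L) {
    stop("`frames` must be an H x W x C x N array", call. = FALSE)
  }
  if (fps <= 0) stop("`fps` must be positive", call. = FALSE)
  structure(list(frames = frames, fps = fps), class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack> %d frames of %dx%d px, %d channel(s) @ %g fps\n",
              d[4], d[1], d[2], d[3], x$fps))
  invisible(x)
}

#' @rdname frame_stack
#' @param x a `frame_stack`.
#' @export
n_frames <- function(x) dim(x$frames)[4]

#' Region of interest within a frame
#'
#' Either a centred patch keeping a fraction of the frame's height and
#' width, or an explicit rectangle. Coordinates are 0-based and rectangles
#' half-open, `[row0, row1) x [col0, col1)`.
#'
#' @param center_fraction fraction of height/width retained around the
#'   frame centre (default 0.5). Ignored when `rect` is given.
#' @param rect optional integer vector `c(row0, row1, col0, col1)`,
#'   0-based, half-open.
#' @return An object of class `roi`.
#' @export
roi <- function(center_fraction = 0.5, rect = NULL) {
  if (is.null(rect)) {
    stopifnot(center_fraction > 0, center_fraction <= 1)
  } else {
    stopifnot(length(rect) == 4, rect[2] > rect[1], rect[4] > rect[3])
  }
  structure(list(center_fraction = center_fraction, rect = rect),
            class = "roi")
}

# resolve an roi to 1-based inclusive row/col index ranges for H x W frames
roi_indices <- function(r, height, width) {
  if (!is.null(r$rect)) {
    rows <- (r$rect[1] + 1):r$rect[2]
    cols <- (r$rect[3] + 1):r$rect[4]
  } else {
    hh <- max(1L, round(height * r$center_fraction))
    ww <- max(1L, round(width * r$center_fraction))
    r0 <- floor((height - hh) / 2) + 1L
    c0 <- floor((width - ww) / 2) + 1L
    rows <- r0:(r0 + hh - 1L)
    cols <- c0:(c0 + ww - 1L)
  }
  if (min(rows) < 1 || max(rows) > height || min(cols) < 1 || max(cols) > width) {
    stop("ROI does not fit inside the frame", call. = FALSE)
  }
  list(rows = rows, cols = cols)
}

#' Extract a PPG time series from video frames by ROI pixel averaging
#'
#' For every frame, each channel's sample is the arithmetic mean of the
#' region-of-interest pixels of that channel; the result is a signal
#' sampled at the frame rate. This is the classic pixel-averaging
#' extraction of video-PPG from a fingertip recording.
#'
#' @param stack a [frame_stack()].
#' @param region a [roi()] (default: centred patch keeping half the frame).
#' @return A [ppg_signal()] with one channel per colour channel and
#'   `fs = fps`.
#' @examples
#' cfg <- sim_config(fs = 30, duration = 2, seed = 3)
#' rec <- gen_ppg(cfg, gen_ecg(cfg)$r_peaks)
#' fr <- gen_frames(rec$signal, height = 16, width = 16, spatial_sd = 1)
#' extract_ppg(fr)
#' @export
extract_ppg <- function(stack, region = roi()) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$frames)
  if (d[4] < 2) stop("need at least 2 frames", call. = FALSE)
  idx <- roi_indices(region, d[1], d[2])
  sub <- stack$frames[idx$rows, idx$cols, , , drop = FALSE]
  # mean over rows and cols -> channels x frames
  m <- apply(sub, c(3, 4), mean)
  chn <- if (d[3] == 3) c("red", "green", "blue") else paste0("ch", seq_len(d[3]))
  ppg_signal(t(m), fs = stack$fps, channels = chn)
}

#' Read a directory of PNG frames as a frame stack
#'
#' Frames are read in lexicographic filename order; all frames must share
#' the same dimensions. Pixel values are rescaled from PNG's unit range to
#' 0-255 intensities.
#'
#' @param dir directory containing `.png` files.
#' @param fps frames per second of the recording.
#' @return A [frame_stack()].
#' @export
read_frame_dir <- function(dir, fps) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0) stop("no .png frames in ", dir, call. = FALSE)
  imgs <- lapply(files, png::readPNG)
  dims <- vapply(imgs, function(im) {
    d <- dim(im)
    if (length(d) == 2) d <- c(d, 1L)
    d[1:3]
  }, integer(3))
  if (any(dims != dims[, 1])) stop("inconsistent frame shapes", call. = FALSE)
  d <- dims[, 1]
  frames <- array(0, dim = c(d, length(imgs)))
  for (i in seq_along(imgs)) {
    im <- imgs[[i]]
    if (length(dim(im)) == 2) dim(im) <- c(dim(im), 1L)
    frames[, , , i] <- im[, , seq_len(d[3])] * 255
  }
  frame_stack(frames, fps = fps)
}

#' Write a frame stack as a directory of PNG frames
#'
#' Counterpart of [read_frame_dir()]; intensities are clamped to 0-255 and
#' stored at 8-bit precision.
#'
#' @param stack a [frame_stack()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_frame_dir <- function(stack, dir) {
  stopifnot(inherits(stack, "frame_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- n_frames(stack)
  width <- max(5L, nchar(as.character(n)))
  for (i in seq_len(n)) {
    im <- stack$frames[, , , i, drop = TRUE]
    im <- pmin(pmax(im / 255, 0), 1)
    png::writePNG(im, file.path(dir, sprintf(paste0("frame_%0", width, "d.png"), i)))
  }
  invisible(dir)
}
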