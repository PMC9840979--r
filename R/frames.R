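#' Frame-sequence video container
#'
#' A `strif_frames` object holds a video as an integer pixel matrix with one
#' column per frame. Within a column, pixels are stored plane-major (all of
#' channel 1, then channel 2, ...), column-major within a plane, on the
#' 0--255 8-bit scale. This flat layout keeps whole-video operations (frame
#' differencing, noise injection) vectorisable.
#'
#' @param pix integer matrix, `h*w*channels` rows by `n_frames` columns.
#' @param h,w frame height and width in pixels.
#' @param channels 1 (grayscale) or 3 (RGB).
#' @param fps frames per second.
#' @return An object of class `strif_frames`.
#' @export
strif_frames <- function(pix, h, w, channels = 1L, fps = 30) {
  stopifnot(is.matrix(pix), is_count(h), is_count(w),
            channels %in% c(1L, 3L), is.numeric(fps), fps > 0)
  if (nrow(pix) != h * w * channels)
    stop_param("pixel matrix has %d rows; expected h*w*channels = %d",
               nrow(pix), h * w * channels)
  if (!is.integer(pix)) storage.mode(pix) <- "integer"
  structure(list(pix = pix, h = as.integer(h), w = as.integer(w),
                 channels = as.integer(channels), fps = fps),
            class = "strif_frames")
}

#' @export
print.strif_frames <- function(x, ...) {
  cat(sprintf("<strif_frames> %d x %d px, %d channel(s), %d frames @ %g fps (%.1f s)\n",
              x$h, x$w, x$channels, n_frames(x), x$fps, n_frames(x) / x$fps))
  invisible(x)
}

#' Number of frames in a video
#' @param frames a `strif_frames` object.
#' @return Integer frame count.
#' @export
n_frames <- function(frames) ncol(frames$pix)

#' Extract one frame as an array
#'
#' @param frames a `strif_frames` object.
#' @param t frame index (1-based).
#' @return `h x w` matrix (grayscale) or `h x w x 3` array (RGB), 0--255.
#' @export
get_frame <- function(frames, t) {
  stopifnot(inherits(frames, "strif_frames"), is_count(t), t <= n_frames(frames))
  v <- frames$pix[, t]
  if (frames$channels == 1L) matrix(v, frames$h, frames$w)
  else array(v, dim = c(frames$h, frames$w, 3L))
}

#' Convert a frame to grayscale by fixed luma weights
#'
#' RGB frames are collapsed with the standard luma weighting
#' (0.299, 0.587, 0.114); grayscale frames pass through.
#'
#' @param frame `h x w` matrix or `h x w x 3` array, 0--255.
#' @return `h x w` numeric matrix.
#' @export
to_gray <- function(frame) {
  if (is.matrix(frame)) return(frame)
  stopifnot(length(dim(frame)) == 3L, dim(frame)[3] == 3L)
  LUMA[1] * frame[, , 1] + LUMA[2] * frame[, , 2] + LUMA[3] * frame[, , 3]
}

# weights for cpp_region_trace: luma for RGB, 1 for grayscale
gray_weights <- function(frames) if (frames$channels == 3L) LUMA else 1.0

#' Write a video as a numbered PNG frame directory
#'
#' Frames are written as `frame_000000.png`, `frame_000001.png`, ...
#' (0-based numbering, matching the ground-truth JSON convention).
#'
#' @param frames a `strif_frames` object.
#' @param dir output directory (created if missing).
#' @return Invisibly, the vector of file paths.
#' @export
write_frames <- function(frames, dir) {
  stopifnot(inherits(frames, "strif_frames"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- n_frames(frames)
  paths <- file.path(dir, sprintf("frame_%06d.png", seq_len(n) - 1L))
  for (t in seq_len(n)) {
    f <- get_frame(frames, t) / 255
    png::writePNG(f, target = paths[t])
  }
  invisible(paths)
}

#' Read a numbered PNG/TIFF frame directory as a video
#'
#' @param dir directory of numbered frame images (sorted lexically).
#' @param fps frames per second of the recording.
#' @return A `strif_frames` object.
#' @export
read_frames <- function(dir, fps = 30) {
  paths <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(paths) == 0)
    stop_param("no PNG frames found in %s", dir)
  f1 <- png::readPNG(paths[1])
  d <- dim(f1)
  channels <- if (length(d) == 2L) 1L else min(d[3], 3L)
  h <- d[1]; w <- d[2]
  pix <- matrix(0L, h * w * channels, length(paths))
  for (t in seq_along(paths)) {
    f <- png::readPNG(paths[t])
    if (channels == 3L && length(dim(f)) == 3L) f <- f[, , 1:3]
    pix[, t] <- as.integer(round(as.vector(f) * 255))
  }
  strif_frames(pix, h, w, channels, fps)
}

# 0-based within-plane linear indices of a square ROI (top, left, side),
# 1-based inputs
roi_indices <- function(roi, h) {
  rows <- roi$top:(roi$top + roi$side - 1L)
  cols <- roi$left:(roi$left + roi$side - 1L)
  as.integer(outer(rows - 1L, (cols - 1L) * h, "+"))
}
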