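#' Raw frame-differencing motion trace over an ROI
#'
#' Motion activity is the mean absolute grayscale pixel difference between
#' frames `t` and `t - stride` over the ROI, in intensity units per pixel.
#' Per-pixel normalisation keeps flies with different ROI sizes comparable.
#'
#' @param frames a [strif_frames()] video with at least `stride + 1` frames.
#' @param roi list with `top`, `left`, `side` (1-based pixel coordinates),
#'   or `NULL` for the whole frame.
#' @param stride frame lag: 1 for consecutive-frame activity, 2 for the
#'   alternating-frame differencing used by struggle speed.
#' @return Numeric vector of length `n_frames - stride`.
#' @export
frame_difference_trace <- function(frames, roi = NULL, stride = 1L) {
  stopifnot(inherits(frames, "strif_frames"), stride >= 1)
  if (n_frames(frames) < stride + 1)
    stop_param("need at least %d frames", stride + 1)
  idx <- if (is.null(roi)) seq_len(frames$h * frames$w) - 1L
         else roi_indices(roi, frames$h)
  cpp_region_trace(frames$pix, as.integer(idx), frames$h * frames$w,
                   frames$channels, gray_weights(frames), as.integer(stride))
}

#' Denoise a motion trace
#'
#' Temporal median filter (shrunken windows at the edges) followed by a
#' minimum-difference floor: values at or below `min_diff_floor` are set to
#' zero. The floor removes the constant pedestal that pixel noise puts
#' under every frame difference.
#'
#' @param x raw activity series.
#' @param median_window odd window length >= 3 (frames).
#' @param min_diff_floor floor in intensity/pixel; values `<=` it become 0.
#' @return Denoised series, same length.
#' @export
denoise_trace <- function(x, median_window = 5, min_diff_floor = 0) {
  stopifnot(min_diff_floor >= 0)
  if (median_window < 3 || median_window %% 2 == 0)
    stop_param("median_window must be odd and >= 3")
  if (length(x) == 0) return(x)
  y <- if (length(x) > median_window)
    as.numeric(stats::runmed(x, median_window, endrule = "median"))
  else rep(median(x), length(x))
  y[y <= min_diff_floor] <- 0
  y
}

#' Background-derived noise floor for an ROI trace
#'
#' An ROI trace averages over far fewer pixels than the whole-frame
#' background trace, so the background's own upper quantile badly
#' understates the noise level an ROI mean can reach (the ROI mean has
#' `sqrt(n_bg/n_roi)` times the background's spread, and pixel noise is
#' heavy-tailed, not Gaussian). The floor is therefore estimated
#' empirically at ROI scale: the background pixels are split into disjoint
#' blocks of `n_roi_px` pixels each, every block's frame-difference trace
#' is denoised with the same median filter as the fly traces, and the
#' floor is `margin` times the `q` quantile of the pooled block samples.
#' With `q = 1` (default) that is the maximum noise excursion ever
#' observed at ROI size, so a static fly essentially never crosses it.
#'
#' @param frames a [strif_frames()] video.
#' @param bg_idx 1-based within-frame indices of background pixels.
#' @param n_roi_px number of pixels in the ROI.
#' @param n_blocks number of disjoint background blocks (capped by the
#'   available background pixels).
#' @param median_window median filter window applied to block traces.
#' @param q quantile of the pooled block-trace samples.
#' @param margin safety multiplier on the quantile.
#' @return Scalar floor in intensity/pixel.
#' @export
noise_floor <- function(frames, bg_idx, n_roi_px, n_blocks = 8,
                        median_window = 5, q = 1, margin = 1.2) {
  n_blocks <- max(1L, min(n_blocks, length(bg_idx) %/% n_roi_px))
  samples <- unlist(lapply(seq_len(n_blocks), function(b) {
    ix <- bg_idx[seq(b, length(bg_idx), by = n_blocks)][seq_len(n_roi_px)]
    denoise_trace(cpp_region_trace(frames$pix, as.integer(ix - 1L),
                                   frames$h * frames$w, frames$channels,
                                   gray_weights(frames), 1L),
                  median_window, 0)
  }))
  margin * quantile(samples, q, names = FALSE)
}

#' Compute per-fly motion traces for a video
#'
#' For each detected fly: consecutive-frame (stride-1) and alternating-frame
#' (stride-2) activity over its ROI; plus one shared background trace over
#' pixels outside all ROIs, and flash detection from background RGB jumps
#' (RGB videos only).
#'
#' @param frames a [strif_frames()] video.
#' @param detections a `fly_detections` table from [detect_flies()].
#' @param bg_sample maximum number of background pixels used (subsampled
#'   deterministically for speed); `Inf` uses all.
#' @param denoise apply [denoise_trace()] with a background-derived floor.
#' @param median_window median filter window (frames).
#' @param excise_flash zero out activity within `median_window` frames of a
#'   detected flash (the global jump is not fly motion).
#' @return A list of `motion_trace` objects (one per fly), each with
#'   fields `fly_id`, `fps`, `activity`, `activity2` (stride-2), `raw`,
#'   `background`, `flash_frame`, `n_frames`, `floor`.
#' @export
motion_traces <- function(frames, detections, bg_sample = 4000,
                          denoise = TRUE, median_window = 5,
                          excise_flash = TRUE) {
  stopifnot(inherits(frames, "strif_frames"))
  h <- frames$h; w <- frames$w
  n <- n_frames(frames)
  # background = pixels outside all ROIs
  inroi <- logical(h * w)
  for (i in seq_len(nrow(detections)))
    inroi[roi_indices(detection_roi(detections, detections$fly_id[i]), h) + 1L] <- TRUE
  bg_idx <- which(!inroi)
  if (length(bg_idx) == 0) stop_param("no background pixels outside ROIs")
  if (length(bg_idx) > bg_sample)
    bg_idx <- bg_idx[round(seq(1, length(bg_idx), length.out = bg_sample))]
  background <- cpp_region_trace(frames$pix, as.integer(bg_idx - 1L),
                                 h * w, frames$channels,
                                 gray_weights(frames), 1L)
  flash <- if (frames$channels == 3L)
    detect_flash(frames, detections = detections, bg_idx = bg_idx)
  else NULL
  flash_frame <- flash$frame

  # one floor per distinct ROI size (usually all flies share one)
  floors <- new.env()
  floor_for <- function(n_px) {
    key <- as.character(n_px)
    if (is.null(floors[[key]]))
      floors[[key]] <- noise_floor(frames, bg_idx, n_px,
                                   median_window = median_window)
    floors[[key]]
  }
  lapply(detections$fly_id, function(f) {
    roi <- detection_roi(detections, f)
    raw <- frame_difference_trace(frames, roi, 1L)
    raw2 <- frame_difference_trace(frames, roi, 2L)
    floor_f <- 0
    act <- raw
    if (denoise) {
      floor_f <- floor_for(roi$side^2)
      act <- denoise_trace(raw, median_window, floor_f)
      raw2 <- denoise_trace(raw2, median_window, floor_f)
    }
    if (excise_flash && !is.null(flash_frame)) {
      cut <- pmax(1, flash_frame - median_window):pmin(length(act), flash_frame + median_window)
      act[cut] <- 0
      cut2 <- pmax(1, flash_frame - median_window):pmin(length(raw2), flash_frame + median_window)
      raw2[cut2] <- 0
    }
    structure(list(fly_id = f, fps = frames$fps, activity = act,
                   activity2 = raw2, raw = raw, background = background,
                   flash_frame = flash_frame, n_frames = n,
                   floor = floor_f),
              class = "motion_trace")
  })
}

#' @export
print.motion_trace <- function(x, ...) {
  cat(sprintf("<motion_trace> fly %s: %d samples @ %g fps, mean activity %.3g%s\n",
              x$fly_id, length(x$activity), x$fps, mean(x$activity),
              if (!is.null(x$flash_frame)) sprintf(", flash @ frame %d", x$flash_frame) else ""))
  invisible(x)
}

#' Struggle speed (alternating-frame motion) of one fly
#'
#' Mean absolute ROI pixel difference between frames `t` and `t - 2`
#' ("alternating frames"), averaged over frames inside active epochs. Note
#' the stride-2 aliasing consequence: motion that oscillates with exact
#' period 2 frames is invisible to this statistic.
#'
#' @param trace a `motion_trace` (uses its stride-2 series), or a
#'   [strif_frames()] video together with `roi`.
#' @param ethogram a `strif_ethogram` defining the active-epoch support.
#' @param roi required when `trace` is a video.
#' @param over `"active"` averages over active epochs (default);
#'   `"all"` over the whole assay.
#' @param window optional `(start, end)` seconds restriction.
#' @return Scalar speed (intensity/pixel/2-frames). If the support is
#'   empty, 0 with attribute `no_activity = TRUE`.
#' @export
strif_speed <- function(trace, ethogram, roi = NULL,
                        over = c("active", "all"), window = NULL) {
  over <- match.arg(over)
  if (inherits(trace, "strif_frames")) {
    stopifnot(!is.null(roi))
    s2 <- frame_difference_trace(trace, roi, 2L)
    fps <- trace$fps
  } else {
    s2 <- trace$activity2
    fps <- trace$fps
  }
  # stride-2 sample i (1-based) spans frames i..i+2; midpoint time i/fps
  t_mid <- seq_along(s2) / fps
  keep <- rep(over == "all", length(s2))
  if (over == "active") {
    eps <- as.data.frame(ethogram)
    act <- eps[eps$state == "active", , drop = FALSE]
    for (i in seq_len(nrow(act)))
      keep <- keep | (t_mid >= act$start[i] & t_mid < act$end[i])
  }
  if (!is.null(window))
    keep <- keep & t_mid >= window[1] & t_mid < window[2]
  if (!any(keep)) return(structure(0, no_activity = TRUE))
  mean(s2[keep])
}

#' Detect the optogenetic flash onset in an RGB video
#'
#' Tracks per-frame background means of each colour channel and flags the
#' first frame whose jump from the previous frame exceeds `k_sd` times the
#' rolling standard deviation of recent jumps (with an absolute floor
#' `min_jump` to guard against a degenerate zero-variance history).
#'
#' @param frames an RGB [strif_frames()] video.
#' @param detections optional `fly_detections`; background excludes ROIs.
#' @param bg_idx optional precomputed 1-based background pixel indices.
#' @param k_sd jump threshold in rolling-SD multiples.
#' @param window rolling window length (frames).
#' @param min_jump absolute minimum jump (intensity units).
#' @return `NULL` if no flash; else a list with `frame` (1-based index of
#'   the first illuminated frame), `channel`, and `pre_illuminated` flag
#'   (jump at the very first frame pair).
#' @export
detect_flash <- function(frames, detections = NULL, bg_idx = NULL,
                         k_sd = 5, window = 30, min_jump = 3) {
  stopifnot(inherits(frames, "strif_frames"))
  if (frames$channels != 3L)
    stop_param("flash detection needs an RGB video")
  h <- frames$h; w <- frames$w
  if (is.null(bg_idx)) {
    inroi <- logical(h * w)
    if (!is.null(detections))
      for (i in seq_len(nrow(detections)))
        inroi[roi_indices(detection_roi(detections, detections$fly_id[i]), h) + 1L] <- TRUE
    bg_idx <- which(!inroi)
    if (length(bg_idx) > 4000)
      bg_idx <- bg_idx[round(seq(1, length(bg_idx), length.out = 4000))]
  }
  m <- cpp_region_channel_means(frames$pix, as.integer(bg_idx - 1L),
                                h * w, 3L)
  n <- nrow(m)
  if (n < 2) return(NULL)
  d <- abs(m[-1, , drop = FALSE] - m[-n, , drop = FALSE])
  for (t in seq_len(n - 1)) {
    for (ch in 1:3) {
      prior <- d[seq_len(max(t - 1, 0)), ch]
      prior <- utils::tail(prior, window)
      thr <- if (length(prior) >= 5) max(k_sd * sd(prior), min_jump) else min_jump
      if (d[t, ch] > thr) {
        return(list(frame = t + 1L, channel = c("R", "G", "B")[ch],
                    pre_illuminated = t == 1L))
      }
    }
  }
  NULL
}

#' Export motion traces to CSV
#'
#' One row per frame per fly (`fly_id`, `frame`, `t_seconds`, `activity`,
#' `background`), plus a flash table written alongside when a flash was
#' detected.
#'
#' @param traces list of `motion_trace` objects.
#' @param path output CSV path; the flash table goes to
#'   `<path>_flash.csv`.
#' @return Invisibly, `path`.
#' @export
write_traces <- function(traces, path) {
  rows <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(fly_id = tr$fly_id, frame = seq_along(tr$activity) + 1L,
               t_seconds = seq_along(tr$activity) / tr$fps,
               activity = tr$activity,
               background = tr$background)
  }))
  write.csv(rows, path, row.names = FALSE)
  fl <- traces[[1]]$flash_frame
  if (!is.null(fl)) {
    write.csv(data.frame(flash_frame = fl,
                         flash_seconds = (fl - 1) / traces[[1]]$fps),
              sub("\\.csv$", "_flash.csv", path), row.names = FALSE)
  }
  invisible(path)
}
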