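# ethogram: activity/immobility segmentation under the 5-second rule and
# the struggle metrics computed from it

new_ethogram <- function(epochs, assay_duration, fly_id = 1L, fps = NA) {
  rownames(epochs) <- NULL
  structure(epochs, assay_duration = assay_duration, fly_id = fly_id,
            fps = fps, class = c("strif_ethogram", "data.frame"))
}

#' @export
print.strif_ethogram <- function(x, ...) {
  cat(sprintf("<strif_ethogram> fly %s: %d epochs over %.1f s\n",
              attr(x, "fly_id"), nrow(x), attr(x, "assay_duration")))
  print(as.data.frame(x), ...)
  invisible(x)
}

# merge same-state neighbours and absorb short inactive epochs that have
# an active neighbour; epochs is a data.frame(state, start, end)
normalize_epochs <- function(epochs, min_immobility) {
  repeat {
    # coalesce identical neighbours
    if (nrow(epochs) > 1) {
      same <- c(FALSE, epochs$state[-1] == epochs$state[-nrow(epochs)])
      if (any(same)) {
        first <- which(!same)
        epochs <- data.frame(
          state = epochs$state[first],
          start = epochs$start[first],
          end = epochs$end[c(first[-1] - 1L, nrow(epochs))])
      }
    }
    short <- which(epochs$state == "inactive" &
                   (epochs$end - epochs$start) < min_immobility)
    if (nrow(epochs) <= 1 || length(short) == 0) break
    epochs$state[short] <- "active"  # absorbed into surrounding activity
  }
  rownames(epochs) <- NULL
  epochs
}

#' Segment a motion trace into activity and immobility epochs
#'
#' Frames with activity above `activity_threshold` are raw-active. Maximal
#' raw-inactive runs shorter than `min_immobility` are merged into the
#' surrounding activity (quiescence under five seconds does not count as
#' immobility); the remaining runs become inactive epochs. Epoch boundaries
#' are frame-index / fps; the epochs tile `[0, n_frames/fps]` exactly.
#'
#' @param trace a `motion_trace`, or a numeric activity series (then `fps`
#'   is required).
#' @param activity_threshold motion threshold in intensity/pixel; on a
#'   denoised (floored) trace, 0 means any surviving motion is activity.
#' @param min_immobility immobility rule threshold in seconds.
#' @param fps frames per second (taken from the trace if given).
#' @return A `strif_ethogram`: data frame `(state, start, end)` in seconds
#'   with attributes `assay_duration`, `fly_id`, `fps`.
#' @export
classify_states <- function(trace, activity_threshold = 0,
                            min_immobility = 5, fps = NULL) {
  if (inherits(trace, "motion_trace")) {
    x <- trace$activity; fps <- trace$fps; fly_id <- trace$fly_id
    n_fr <- trace$n_frames
  } else {
    x <- as.numeric(trace); fly_id <- 1L
    if (is.null(fps)) stop_param("fps required for a bare activity series")
    n_fr <- length(x) + 1L
  }
  if (length(x) == 0) stop_param("empty trace")
  stopifnot(activity_threshold >= 0, min_immobility > 0)
  raw_active <- x > activity_threshold
  r <- runs_of(raw_active)
  # sample i spans [(i-1)/fps, i/fps); extend the last epoch to n_fr/fps
  epochs <- data.frame(state = ifelse(r$value, "active", "inactive"),
                       start = (r$start - 1) / fps, end = r$end / fps)
  epochs$end[nrow(epochs)] <- n_fr / fps
  epochs <- normalize_epochs(epochs, min_immobility)
  new_ethogram(epochs, assay_duration = n_fr / fps, fly_id = fly_id,
               fps = fps)
}

#' Struggle metrics for one fly over a window
#'
#' Totals, epoch counts, mean epoch durations, the activity:inactivity
#' ratio (the primary struggle statistic) and, when a trace is supplied,
#' the struggle speed over active epochs in the window. Epochs straddling
#' the window edges are truncated at the edge. The ratio is flagged
#' undefined (`NA` with `ratio_defined = FALSE`) when the fly never went
#' immobile, rather than reported as infinite.
#'
#' @param ethogram a `strif_ethogram`.
#' @param trace optional `motion_trace` for the speed statistic.
#' @param window `(start, end)` seconds; `NULL` for the full assay.
#' @param label window label stored in the output (`"full"`,
#'   `"before_flash"`, `"after_flash"`, ...).
#' @return A one-row `strif_metrics` data frame.
#' @export
compute_metrics <- function(ethogram, trace = NULL, window = NULL,
                            label = "full") {
  dur <- attr(ethogram, "assay_duration")
  if (is.null(window)) window <- c(0, dur)
  if (window[2] <= window[1]) stop_param("zero-length window")
  if (window[1] < -1e-9 || window[2] > dur + 1e-9)
    stop_param("window outside the assay")
  eps <- as.data.frame(ethogram)
  eps$start <- pmax(eps$start, window[1])
  eps$end <- pmin(eps$end, window[2])
  eps <- eps[eps$end > eps$start, , drop = FALSE]
  wlen <- window[2] - window[1]
  a <- eps[eps$state == "active", , drop = FALSE]
  i <- eps[eps$state == "inactive", , drop = FALSE]
  total_active <- sum(a$end - a$start)
  total_inactive <- wlen - total_active  # exact conservation
  ratio_defined <- total_inactive > 1e-12
  speed <- if (!is.null(trace))
    as.numeric(strif_speed(trace, ethogram, window = window)) else NA_real_
  out <- data.frame(
    fly_id = attr(ethogram, "fly_id"),
    window = label,
    window_start = window[1], window_end = window[2],
    total_active = total_active, total_inactive = total_inactive,
    ratio = if (ratio_defined) total_active / total_inactive else NA_real_,
    ratio_defined = ratio_defined,
    n_active_epochs = nrow(a), n_inactive_epochs = nrow(i),
    mean_active_duration = if (nrow(a)) total_active / nrow(a) else 0,
    mean_inactive_duration = if (nrow(i)) total_inactive / nrow(i) else 0,
    strif_speed = speed)
  class(out) <- c("strif_metrics", "data.frame")
  out
}

#' Split an ethogram at the flash into before/after metrics
#'
#' The epoch containing `flash_time` is split at the flash; the post-flash
#' fragment (and the rest of the after-window sequence) is re-evaluated
#' against the immobility rule, so an inactive fragment shorter than the
#' rule is absorbed into activity.
#'
#' @param ethogram a `strif_ethogram`.
#' @param trace optional `motion_trace` for speed statistics.
#' @param flash_time flash onset in seconds (strictly inside the assay).
#' @param min_immobility immobility rule threshold in seconds.
#' @return List with elements `before` and `after` (both `strif_metrics`),
#'   and attribute `after_ethogram`.
#' @export
split_before_after <- function(ethogram, trace = NULL, flash_time,
                               min_immobility = 5) {
  dur <- attr(ethogram, "assay_duration")
  if (flash_time <= 0 || flash_time >= dur)
    stop_param("degenerate window: flash must lie strictly inside (0, %g)", dur)
  before <- compute_metrics(ethogram, trace, c(0, flash_time),
                            label = "before_flash")
  eps <- as.data.frame(ethogram)
  eps$start <- pmax(eps$start, flash_time)
  eps <- eps[eps$end > eps$start, , drop = FALSE]
  eps <- normalize_epochs(eps, min_immobility)
  after_eth <- new_ethogram(eps, assay_duration = dur,
                            fly_id = attr(ethogram, "fly_id"),
                            fps = attr(ethogram, "fps"))
  after <- compute_metrics(after_eth, trace, c(flash_time, dur),
                           label = "after_flash")
  structure(list(before = before, after = after),
            after_ethogram = after_eth)
}

#' Pooled duration histogram of activity and inactivity epochs
#'
#' Normalized per-state histogram of epoch durations in half-open bins
#' `[k*bin, (k+1)*bin)`.
#'
#' @param ethograms a `strif_ethogram` or list of them.
#' @param bin bin width in seconds.
#' @return Data frame `(state, bin_lo, bin_hi, count, prob)`; `prob` sums
#'   to 1 within each state.
#' @export
duration_histogram <- function(ethograms, bin = 5) {
  if (inherits(ethograms, "strif_ethogram")) ethograms <- list(ethograms)
  stopifnot(length(ethograms) >= 1)
  eps <- do.call(rbind, lapply(ethograms, as.data.frame))
  eps$durn <- eps$end - eps$start
  mx <- max(eps$durn)
  nb <- floor(mx / bin) + 1L
  out <- do.call(rbind, lapply(c("active", "inactive"), function(st) {
    d <- eps$durn[eps$state == st]
    if (length(d) == 0) return(NULL)
    k <- pmin(floor(d / bin), nb - 1L)
    cnt <- tabulate(k + 1L, nb)
    data.frame(state = st, bin_lo = (seq_len(nb) - 1L) * bin,
               bin_hi = seq_len(nb) * bin, count = cnt,
               prob = cnt / sum(cnt))
  }))
  rownames(out) <- NULL
  out
}

#' Export ethograms as tidy CSV
#'
#' @param ethograms list of `strif_ethogram`s.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_ethograms <- function(ethograms, path) {
  if (inherits(ethograms, "strif_ethogram")) ethograms <- list(ethograms)
  rows <- do.call(rbind, lapply(ethograms, function(e) {
    cbind(fly_id = attr(e, "fly_id"), as.data.frame(e))
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
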