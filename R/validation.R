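# ground-truth comparison utilities for synthetic fixtures

#' Compare a recovered ethogram against ground truth
#'
#' Used to validate the pipeline on synthetic renders: matches interior
#' epoch boundaries of the truth ethogram to recovered boundaries within a
#' tolerance, and computes the state-wise total-time error as a fraction
#' of the assay duration. The truth should already have the immobility
#' rule applied (see [program_to_ethogram()]), since sub-rule quiescence
#' is not recoverable by construction.
#'
#' @param recovered,truth `strif_ethogram` objects over the same assay.
#' @param tol boundary matching tolerance in seconds.
#' @return List: `n_boundaries` (interior truth boundaries), `n_matched`
#'   (within `tol` of a recovered boundary), `boundary_fraction`,
#'   `state_sequence_equal`, `active_time_error` (fraction of assay
#'   duration), `duration`.
#' @export
compare_to_truth <- function(recovered, truth, tol = 1) {
  dur <- attr(truth, "assay_duration")
  tb <- truth$end[-nrow(truth)]
  rb <- recovered$end[-nrow(recovered)]
  matched <- if (length(tb) == 0) integer(0)
  else vapply(tb, function(b) length(rb) > 0 && min(abs(rb - b)) <= tol, NA)
  truth_active <- sum(truth$end[truth$state == "active"] -
                      truth$start[truth$state == "active"])
  rec_active <- sum(recovered$end[recovered$state == "active"] -
                    recovered$start[recovered$state == "active"])
  list(n_boundaries = length(tb), n_matched = sum(matched),
       boundary_fraction = if (length(tb)) mean(matched) else 1,
       state_sequence_equal = identical(recovered$state, truth$state),
       active_time_error = abs(truth_active - rec_active) / dur,
       duration = dur)
}

#' Ground-truth recovery study on synthetic videos
#'
#' Renders a batch of multi-fly videos with known mixed behavior programs
#' (heterogeneous epoch means and flailing amplitudes across flies),
#' optionally corrupted by salt-and-pepper noise, runs the full pipeline
#' on each, and scores epoch-boundary recovery and state-time error
#' against the programmed ground truth.
#'
#' @param n_videos number of videos.
#' @param seed master seed; video v uses `seed * 1000 + v` offsets.
#' @param n_flies,duration,fps,frame_size,noise render conditions.
#' @param tol boundary matching tolerance in seconds.
#' @return List: `boundary_fraction` (pooled share of interior ground-truth
#'   boundaries matched within `tol`), `mean_time_error` and
#'   `max_time_error` (state-time error as fraction of assay duration),
#'   `n_boundaries`, `per_fly` data frame.
#' @export
recovery_study <- function(n_videos = 100, seed = 1, n_flies = 6,
                           duration = 300, fps = 30,
                           frame_size = c(120, 160), noise = 0.01,
                           tol = 1) {
  mixes <- list(c(20, 10), c(15, 15), c(30, 8), c(10, 20), c(25, 12),
                c(12, 8))
  amps <- c(2, 3, 4)
  rows <- vector("list", n_videos * n_flies)
  cfg <- strif_config(fps = fps, n_expected_flies = n_flies, seed = seed)
  for (v in seq_len(n_videos)) {
    base <- seed * 1000L + v * 10L
    progs <- lapply(seq_len(n_flies), function(i) {
      m <- mixes[[(v + i) %% length(mixes) + 1]]
      sample_program(duration, m[1], m[2],
                     amplitude = amps[(v + i) %% length(amps) + 1],
                     seed = base + i, fly_id = i)
    })
    spec <- render_spec(frame_size = frame_size, fps = fps,
                        n_flies = n_flies, noise_fraction = noise,
                        seed = base)
    rv <- render_video(progs, spec)
    run <- run_strif(rv$frames, NULL, cfg)
    for (i in seq_len(n_flies)) {
      truth <- program_to_ethogram(progs[[i]])
      cmp <- compare_to_truth(run$ethograms[[i]], truth, tol = tol)
      rows[[(v - 1) * n_flies + i]] <- data.frame(
        video = v, fly = i, n_boundaries = cmp$n_boundaries,
        n_matched = cmp$n_matched, time_error = cmp$active_time_error)
    }
    rm(rv, run)
  }
  per_fly <- do.call(rbind, rows)
  list(boundary_fraction = sum(per_fly$n_matched) / sum(per_fly$n_boundaries),
       mean_time_error = mean(per_fly$time_error),
       max_time_error = max(per_fly$time_error),
       n_boundaries = sum(per_fly$n_boundaries),
       per_fly = per_fly)
}
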