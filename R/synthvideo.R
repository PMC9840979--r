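#' Sample a ground-truth behavior program
#'
#' Generates an alternating sequence of active (flailing) and inactive
#' (immobile) epochs for one simulated restrained fly. Epoch durations are
#' drawn from a shifted exponential: `min_epoch + Exp(mean - min_epoch)`,
#' i.e. the left-truncated exponential whose post-truncation mean equals
#' the requested mean exactly. A mean of `Inf` makes every epoch of that
#' state run to the end of the assay, which yields degenerate single-state
#' programs.
#'
#' @param duration total assay duration in seconds.
#' @param mean_active,mean_inactive mean epoch durations in seconds
#'   (must exceed `min_epoch`; may be `Inf`).
#' @param amplitude blob jitter amplitude in pixels during active epochs
#'   (per-frame displacement is uniform on `-amplitude..amplitude` per axis).
#' @param seed integer seed; the program is reproducible given the seed.
#' @param min_epoch lower truncation of epoch durations in seconds.
#' @param start_state state of the first epoch, `"active"` or `"inactive"`.
#' @param fly_id identifier attached to the program.
#' @return A `behavior_program`: data frame with columns `state`,
#'   `duration`, `amplitude` and attributes `total_duration`, `fly_id`.
#' @export
sample_program <- function(duration, mean_active = 20, mean_inactive = 10,
                           amplitude = 3, seed = NULL, min_epoch = 1,
                           start_state = c("active", "inactive"),
                           fly_id = 1L) {
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0)
    stop_param("duration must be a positive number of seconds")
  if (mean_active <= min_epoch || mean_inactive <= min_epoch)
    stop_param("mean epoch durations must exceed min_epoch = %g s", min_epoch)
  start_state <- match.arg(start_state)
  means <- c(active = mean_active, inactive = mean_inactive)
  with_seed(seed, {
    st <- start_state
    states <- character(0); durs <- numeric(0)
    remaining <- duration
    while (remaining > 0) {
      m <- means[[st]]
      d <- if (is.finite(m)) min_epoch + rexp(1, rate = 1 / (m - min_epoch)) else Inf
      d <- min(d, remaining)
      states <- c(states, st)
      durs <- c(durs, d)
      remaining <- remaining - d
      st <- if (st == "active") "inactive" else "active"
    }
    behavior_program(states, durs,
                     amplitude = ifelse(states == "active", amplitude, 0),
                     fly_id = fly_id)
  })
}

#' Construct a behavior program from explicit epochs
#'
#' @param states character vector of `"active"`/`"inactive"` states;
#'   adjacent states must alternate.
#' @param durations epoch durations in seconds (positive).
#' @param amplitude jitter amplitudes in pixels, recycled; forced to 0 for
#'   inactive epochs.
#' @param fly_id identifier.
#' @return A `behavior_program` object.
#' @export
behavior_program <- function(states, durations, amplitude = 3, fly_id = 1L) {
  stopifnot(length(states) == length(durations), length(states) >= 1)
  if (!all(states %in% c("active", "inactive")))
    stop_param("states must be 'active' or 'inactive'")
  if (any(durations <= 0)) stop_param("epoch durations must be positive")
  if (length(states) > 1 && any(states[-1] == states[-length(states)]))
    stop_param("adjacent epochs must alternate state")
  amplitude <- rep_len(amplitude, length(states))
  amplitude[states == "inactive"] <- 0
  structure(data.frame(state = states, duration = as.numeric(durations),
                       amplitude = as.numeric(amplitude)),
            total_duration = sum(durations), fly_id = fly_id,
            class = c("behavior_program", "data.frame"))
}

#' Total duration of a behavior program
#' @param program a `behavior_program`.
#' @return Duration in seconds.
#' @export
program_duration <- function(program) attr(program, "total_duration")

#' Expected ethogram of a behavior program under the immobility rule
#'
#' Applies the same >= `min_immobility` rule used by [classify_states()] to
#' the ground-truth program: inactive epochs shorter than the rule that
#' have an active neighbour are absorbed into activity. This is the
#' reference against which pipeline recovery is judged, since short
#' programmed quiescence is by definition not immobility.
#'
#' @param program a `behavior_program`.
#' @param min_immobility immobility rule threshold in seconds.
#' @return A `strif_ethogram` object.
#' @export
program_to_ethogram <- function(program, min_immobility = 5) {
  ends <- cumsum(program$duration)
  eps <- data.frame(state = program$state,
                    start = ends - program$duration, end = ends)
  eps <- normalize_epochs(eps, min_immobility)
  new_ethogram(eps, assay_duration = program_duration(program),
               fly_id = attr(program, "fly_id"))
}

#' Rendering specification for synthetic videos
#'
#' @param frame_size frame `(height, width)` in pixels.
#' @param fps frames per second.
#' @param n_flies number of flies.
#' @param fly_radius disk radius of the rendered fly blob in pixels.
#' @param fly_positions optional `n_flies x 2` matrix of `(row, col)`
#'   anchors; defaults to an evenly spaced grid. Positions must be pairwise
#'   separated by more than `4 * fly_radius`.
#' @param background_level,fly_level 8-bit intensities; must differ by at
#'   least 50 units.
#' @param flash_frame optional 1-based frame index at which a global
#'   illumination flash switches on (and stays on).
#' @param flash_shift per-channel additive intensity shift of the flash;
#'   default shifts the red channel only, mimicking red optogenetic light.
#' @param noise_fraction proportion of salt-and-pepper pixels per frame
#'   (must be < 0.05).
#' @param color render RGB (`TRUE`) or grayscale (`FALSE`); defaults to RGB
#'   when a flash is configured, grayscale otherwise.
#' @param seed integer seed for jitter and noise.
#' @return A `render_spec` list.
#' @export
render_spec <- function(frame_size = c(120, 160), fps = 30, n_flies = 6,
                        fly_radius = 6, fly_positions = NULL,
                        background_level = 200, fly_level = 30,
                        flash_frame = NULL, flash_shift = c(40, 0, 0),
                        noise_fraction = 0, color = NULL, seed = 1L) {
  stopifnot(length(frame_size) == 2, all(frame_size > 0), fps > 0,
            is_count(n_flies), fly_radius >= 1)
  if (noise_fraction < 0 || noise_fraction >= 0.05)
    stop_param("noise_fraction must be in [0, 0.05)")
  if (abs(fly_level - background_level) < 50)
    stop_param("fly_level must differ from background_level by >= 50 units")
  h <- as.integer(frame_size[1]); w <- as.integer(frame_size[2])
  if (is.null(fly_positions)) fly_positions <- default_positions(h, w, n_flies)
  fly_positions <- as.matrix(fly_positions)
  if (nrow(fly_positions) != n_flies)
    stop_param("fly_positions must have one row per fly")
  if (n_flies > 1) {
    dists <- as.matrix(stats::dist(fly_positions))
    diag(dists) <- Inf
    if (min(dists) <= 4 * fly_radius)
      stop_param("fly positions must be pairwise separated by > 4*fly_radius")
  }
  color <- color %||% !is.null(flash_frame)
  if (!is.null(flash_frame))
    stopifnot(is_count(flash_frame))
  structure(list(h = h, w = w, fps = fps, n_flies = as.integer(n_flies),
                 fly_radius = as.integer(fly_radius),
                 fly_positions = fly_positions,
                 background_level = as.integer(background_level),
                 fly_level = as.integer(fly_level),
                 flash_frame = flash_frame,
                 flash_shift = as.integer(rep_len(flash_shift, 3)),
                 noise_fraction = noise_fraction,
                 color = isTRUE(color), seed = as.integer(seed)),
            class = "render_spec")
}

# evenly spaced anchor grid with generous margins
default_positions <- function(h, w, n) {
  ncol_g <- ceiling(sqrt(n * w / h))
  nrow_g <- ceiling(n / ncol_g)
  rows <- round(seq(0.5, nrow_g - 0.5, length.out = nrow_g) / nrow_g * h)
  cols <- round(seq(0.5, ncol_g - 0.5, length.out = ncol_g) / ncol_g * w)
  # raster order (row-major) so anchor k matches detection fly_id k
  g <- expand.grid(col = cols, row = rows)[, c("row", "col")]
  as.matrix(g[seq_len(n), , drop = FALSE])
}

disk_offsets <- function(r) {
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g[g$dr^2 + g$dc^2 <= r^2, , drop = FALSE]
}

#' Render behavior programs as a synthetic multi-fly video
#'
#' Each fly is a filled dark disk on a light background, anchored at its
#' position. During active epochs the disk centre jitters around the anchor
#' by an integer displacement uniform on `-amplitude..amplitude` per axis
#' per frame; during inactive epochs it is static. A configured flash adds
#' `flash_shift` channel-wise to all frames from `flash_frame` on.
#' Salt-and-pepper noise is applied if `spec$noise_fraction > 0`.
#'
#' @param programs list of `behavior_program`s, one per fly; all must share
#'   the same total duration.
#' @param spec a [render_spec()].
#' @return A `strif_render` list: `frames` (a [strif_frames()] video) and
#'   `truth` (programs, anchors, flash frame, seed).
#' @export
render_video <- function(programs, spec) {
  stopifnot(inherits(spec, "render_spec"))
  if (inherits(programs, "behavior_program")) programs <- list(programs)
  if (length(programs) != spec$n_flies)
    stop_param("need %d programs, got %d", spec$n_flies, length(programs))
  durs <- vapply(programs, program_duration, 0)
  if (max(durs) - min(durs) > 1e-9)
    stop_param("all programs must share the same total duration")
  n <- as.integer(round(durs[1] * spec$fps))
  k <- spec$n_flies
  channels <- if (spec$color) 3L else 1L

  jit <- with_seed(spec$seed, {
    jr <- matrix(0L, k, n); jc <- matrix(0L, k, n)
    for (f in seq_len(k)) {
      amp <- epoch_amplitude_per_frame(programs[[f]], n, spec$fps)
      mx <- max(amp)
      if (mx > 0) {
        # guard: jitter must keep the disk inside the frame
        pos <- spec$fly_positions[f, ]
        if (pos[1] - spec$fly_radius - mx < 1 || pos[1] + spec$fly_radius + mx > spec$h ||
            pos[2] - spec$fly_radius - mx < 1 || pos[2] + spec$fly_radius + mx > spec$w)
          stop_param("fly %d: anchor too close to frame edge for amplitude %g", f, mx)
      }
      for (a in setdiff(unique(amp), 0L)) {
        act <- which(amp == a)
        jr[f, act] <- sample(-a:a, length(act), replace = TRUE)
        jc[f, act] <- sample(-a:a, length(act), replace = TRUE)
      }
    }
    list(jr = jr, jc = jc)
  })

  dsk <- disk_offsets(spec$fly_radius)
  lv <- function(x) as.integer(rep_len(x, channels))
  pix <- cpp_render(spec$h, spec$w, n, channels,
                    lv(spec$background_level), lv(spec$fly_level),
                    as.integer(dsk$dr), as.integer(dsk$dc),
                    as.integer(spec$fly_positions[, 1]),
                    as.integer(spec$fly_positions[, 2]),
                    jit$jr, jit$jc,
                    as.integer(spec$flash_frame %||% 0L),
                    spec$flash_shift[seq_len(channels)])
  frames <- strif_frames(pix, spec$h, spec$w, channels, spec$fps)
  if (spec$noise_fraction > 0)
    frames <- inject_noise(frames, spec$noise_fraction,
                           seed = spec$seed + 1L, in_place = TRUE)
  structure(list(frames = frames,
                 truth = list(programs = programs,
                              anchors = spec$fly_positions,
                              flash_frame = spec$flash_frame,
                              fps = spec$fps, seed = spec$seed)),
            class = "strif_render")
}

# per-frame amplitude vector from a program (frame t covers time
# [(t-1)/fps, t/fps); the epoch containing the frame's start time applies)
epoch_amplitude_per_frame <- function(program, n, fps) {
  ends <- cumsum(program$duration)
  t0 <- (seq_len(n) - 1) / fps
  idx <- findInterval(t0, c(0, ends), rightmost.closed = FALSE)
  idx[idx > nrow(program)] <- nrow(program)
  as.integer(round(program$amplitude[idx]))
}

#' Inject salt-and-pepper noise into a video
#'
#' Exactly `round(noise_fraction * h * w)` pixel sites per frame are set to
#' the intensity extremes, half to 255 (salt) and half to 0 (pepper), ties
#' toward salt. RGB sites are overwritten in all channels.
#'
#' @param frames a `strif_frames` video.
#' @param noise_fraction proportion of noisy pixel sites per frame in
#'   `[0, 1)`.
#' @param seed integer seed; noise positions are reproducible.
#' @param in_place internal flag; skips the defensive copy.
#' @return A `strif_frames` video with noise applied.
#' @export
inject_noise <- function(frames, noise_fraction, seed = NULL,
                         in_place = FALSE) {
  stopifnot(inherits(frames, "strif_frames"))
  if (noise_fraction < 0 || noise_fraction >= 1)
    stop_param("noise_fraction must be in [0, 1)")
  nn <- round(noise_fraction * frames$h * frames$w)
  if (nn == 0) return(frames)
  n_salt <- ceiling(nn / 2)
  pix <- frames$pix
  if (!in_place) pix <- pix + 0L  # force a copy before in-place C++ write
  with_seed(seed, cpp_sp_noise(pix, frames$h, frames$w, frames$channels,
                               as.integer(n_salt), as.integer(nn - n_salt)))
  strif_frames(pix, frames$h, frames$w, frames$channels, frames$fps)
}

#' Write ground truth as JSON
#'
#' Frame indices are serialized 0-based; programs are stored as epoch
#' tables.
#'
#' @param truth the `truth` element of a [render_video()] result.
#' @param path output JSON path.
#' @return Invisibly, `path`.
#' @export
write_ground_truth <- function(truth, path) {
  out <- list(
    fps = truth$fps,
    seed = truth$seed,
    flash_frame0 = if (is.null(truth$flash_frame)) NULL
                   else truth$flash_frame - 1L,
    anchors = lapply(seq_len(nrow(truth$anchors)), function(i)
      list(row = truth$anchors[i, 1], col = truth$anchors[i, 2])),
    programs = lapply(truth$programs, function(p)
      list(fly_id = attr(p, "fly_id"),
           total_duration = program_duration(p),
           epochs = data.frame(state = p$state, duration = p$duration,
                               amplitude = p$amplitude))))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read ground truth written by [write_ground_truth()]
#' @param path JSON path.
#' @return A truth list with 1-based flash frame and `behavior_program`s.
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  # read_json simplifies the programs list to a data.frame when uniform
  programs <- if (is.data.frame(x$programs)) {
    lapply(seq_len(nrow(x$programs)), function(i) {
      e <- x$programs$epochs[[i]]
      behavior_program(e$state, e$duration, e$amplitude,
                       fly_id = x$programs$fly_id[i])
    })
  } else {
    lapply(x$programs, function(p)
      behavior_program(p$epochs$state, p$epochs$duration, p$epochs$amplitude,
                       fly_id = p$fly_id))
  }
  list(programs = programs,
       anchors = cbind(row = x$anchors$row, col = x$anchors$col),
       flash_frame = if (length(x$flash_frame0) == 0) NULL
                     else unlist(x$flash_frame0) + 1L,
       fps = x$fps, seed = x$seed)
}
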