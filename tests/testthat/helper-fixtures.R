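# fixtures are generated in code; no binary data ships with the package

# build a strif_frames video from a list of h x w matrices (grayscale) or
# h x w x 3 arrays (RGB)
frames_from_list <- function(lst, fps = 30) {
  d <- dim(lst[[1]])
  channels <- if (length(d) == 2L) 1L else 3L
  pix <- vapply(lst, function(f) as.integer(round(as.vector(f))),
                integer(prod(d)))
  strif_frames(matrix(pix, ncol = length(lst)), d[1], d[2], channels, fps)
}

# a flat frame with filled disks at given (row, col) centres
disk_frame <- function(h, w, centers, radius = 5, bg = 200, fg = 30) {
  f <- matrix(bg, h, w)
  for (i in seq_len(nrow(centers))) {
    for (dr in -radius:radius) for (dc in -radius:radius) {
      if (dr^2 + dc^2 <= radius^2) {
        r <- centers[i, 1] + dr; c <- centers[i, 2] + dc
        if (r >= 1 && r <= h && c >= 1 && c <= w) f[r, c] <- fg
      }
    }
  }
  f
}

# pixel set of a discrete disk, as linear indices (independent oracle for
# frame-difference geometry)
disk_pixels <- function(h, center, radius) {
  px <- c()
  for (dr in -radius:radius) for (dc in -radius:radius)
    if (dr^2 + dc^2 <= radius^2)
      px <- c(px, (center[1] + dr) + (center[2] + dc - 1) * h)
  px
}

# quick single-fly or multi-fly synthetic render
render_fixture <- function(n_flies = 2, duration = 30, fps = 10,
                           mean_active = 8, mean_inactive = 7,
                           amplitude = 2, noise = 0, seed = 1,
                           frame_size = c(60, 80), flash_frame = NULL,
                           radius = 5) {
  progs <- lapply(seq_len(n_flies), function(i)
    sample_program(duration, mean_active, mean_inactive,
                   amplitude = amplitude, seed = seed * 1000 + i,
                   fly_id = i))
  spec <- render_spec(frame_size = frame_size, fps = fps,
                      n_flies = n_flies, fly_radius = radius,
                      noise_fraction = noise, flash_frame = flash_frame,
                      seed = seed)
  render_video(progs, spec)
}

# indicator activity series of a program (1 during active epochs), with
# length n_frames - 1, sample i covering [(i-1)/fps, i/fps)
indicator_trace <- function(program, fps, level = 10) {
  n <- round(program_duration(program) * fps)
  ends <- cumsum(program$duration)
  t0 <- (seq_len(n - 1) - 1) / fps
  idx <- findInterval(t0, c(0, ends), rightmost.closed = FALSE)
  idx[idx > nrow(program)] <- nrow(program)
  ifelse(program$state[idx] == "active", level, 0)
}
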