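#' Walking metrics from a centroid trajectory
#'
#' For the open-field paradigm the tracker supplies per-frame centroid
#' positions in calibrated millimetres (15 mm arenas). Frame speeds are
#' centroid displacement times fps; frames with speed above
#' `immobility_speed_threshold` are raw-active and the same >= 5-second
#' immobility rule as the struggle assay is applied. The activity:
#' inactivity ratio and the average speed are returned.
#'
#' @param trajectory data frame with columns `x`, `y` (mm) and optionally
#'   `t` (seconds); or a matrix with two columns.
#' @param fps frames per second (required when no `t` column).
#' @param immobility_speed_threshold speed threshold in mm/s below which a
#'   frame counts as quiescent.
#' @param min_immobility immobility rule threshold in seconds.
#' @param interpolate linearly interpolate across missing-frame gaps; when
#'   `FALSE`, gaps longer than 1 s are an error.
#' @param over average speed over `"active"` frames (default) or `"all"`.
#' @param fly_id identifier.
#' @return A one-row data frame shaped like [compute_metrics()] output with
#'   an extra `mean_speed` column (mm/s), plus attribute `ethogram`.
#' @export
walking_metrics <- function(trajectory, fps = NULL,
                            immobility_speed_threshold = 0.5,
                            min_immobility = 5, interpolate = FALSE,
                            over = c("active", "all"), fly_id = 1L) {
  over <- match.arg(over)
  trajectory <- as.data.frame(trajectory)
  if (!all(c("x", "y") %in% names(trajectory)))
    names(trajectory)[1:2] <- c("x", "y")
  if ("t" %in% names(trajectory)) {
    tt <- trajectory$t
    if (is.null(fps)) fps <- 1 / median(diff(tt))
    gaps <- diff(tt)
    if (any(gaps > 1 + 1e-9) && !interpolate)
      stop_param("trajectory has gaps > 1 s; set interpolate = TRUE")
    grid <- seq(tt[1], tt[length(tt)], by = 1 / fps)
    trajectory <- data.frame(
      x = approx(tt, trajectory$x, grid, rule = 2)$y,
      y = approx(tt, trajectory$y, grid, rule = 2)$y)
  } else if (is.null(fps)) {
    stop_param("fps required when the trajectory has no time column")
  }
  n <- nrow(trajectory)
  if (n < 2) stop_param("trajectory needs at least 2 points")
  speed <- sqrt(diff(trajectory$x)^2 + diff(trajectory$y)^2) * fps
  eth <- classify_states(speed, activity_threshold = immobility_speed_threshold,
                         min_immobility = min_immobility, fps = fps)
  attr(eth, "fly_id") <- fly_id
  m <- compute_metrics(eth, label = "walking")
  m$fly_id <- fly_id
  keep <- if (over == "all") rep(TRUE, length(speed)) else {
    t_mid <- (seq_along(speed) - 0.5) / fps
    act <- as.data.frame(eth)
    act <- act[act$state == "active", , drop = FALSE]
    k <- rep(FALSE, length(speed))
    for (i in seq_len(nrow(act)))
      k <- k | (t_mid >= act$start[i] & t_mid < act$end[i])
    k
  }
  m$mean_speed <- if (any(keep)) mean(speed[keep]) else 0
  m$strif_speed <- NULL
  structure(m, ethogram = eth)
}
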