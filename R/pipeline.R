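# pipeline orchestration: config, metadata joining, end-to-end runs

#' Experiment configuration
#'
#' Collects every tunable parameter of the pipeline with validated
#' defaults. `seed` is mandatory: all resampling downstream derives from
#' it, which makes whole runs reproducible.
#'
#' @param fps frames per second of the recording.
#' @param n_expected_flies flies per arena.
#' @param min_area,max_area blob size filter (pixels).
#' @param kernel_radius morphological cleaning radius (pixels).
#' @param roi_scale ROI side as multiple of max blob dimension.
#' @param polarity blob polarity, `"dark"` or `"light"`.
#' @param median_window temporal median filter length (frames, odd).
#' @param floor_quantile background quantile defining the motion floor.
#' @param min_immobility immobility rule threshold (seconds).
#' @param n_boot,n_perm,alpha estimation parameters.
#' @param seed integer master seed (mandatory).
#' @param output_dir optional directory for CSV/JSON outputs.
#' @return A validated `strif_config` list.
#' @export
strif_config <- function(fps = 30, n_expected_flies = 6, min_area = 30,
                         max_area = 2000, kernel_radius = 1,
                         roi_scale = 2, polarity = "dark",
                         median_window = 5, floor_quantile = 0.99,
                         min_immobility = 5, n_boot = 5000, n_perm = 10000,
                         alpha = 0.05, seed, output_dir = NULL) {
  if (missing(seed) || !is.numeric(seed))
    stop_param("seed is mandatory in strif_config")
  stopifnot(fps > 0, is_count(n_expected_flies), min_area > 0,
            max_area > min_area, kernel_radius >= 0, roi_scale >= 1,
            polarity %in% c("dark", "light"),
            median_window >= 3, median_window %% 2 == 1,
            floor_quantile > 0, floor_quantile < 1, min_immobility > 0,
            n_boot >= 1000, n_perm >= 1000, alpha > 0, alpha < 1)
  structure(list(fps = fps, n_expected_flies = as.integer(n_expected_flies),
                 min_area = min_area, max_area = max_area,
                 kernel_radius = kernel_radius, roi_scale = roi_scale,
                 polarity = polarity, median_window = median_window,
                 floor_quantile = floor_quantile,
                 min_immobility = min_immobility, n_boot = n_boot,
                 n_perm = n_perm, alpha = alpha, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "strif_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys mirror [strif_config()] arguments.
#' @return A `strif_config`.
#' @export
read_config <- function(path) {
  do.call(strif_config, yaml::read_yaml(path))
}

#' Read an arena metadata table
#'
#' Maps arena positions (raster order of detection) to genotype/condition.
#' Position indices must be unique.
#'
#' @param path CSV with columns `position` plus any of `genotype`,
#'   `condition`, `sex`, `intervention`; or a data frame.
#' @return A validated metadata data frame.
#' @export
read_metadata <- function(path) {
  md <- if (is.data.frame(path)) path else read.csv(path)
  if (!"position" %in% names(md))
    stop_param("metadata needs a 'position' column")
  if (anyDuplicated(md$position))
    stop_param("metadata position indices must be unique")
  md
}

#' Run the full struggle-analysis pipeline on one video
#'
#' detection (first frame, fixed ROIs) -> motion traces with
#' background-derived denoising -> ethograms under the immobility rule ->
#' per-fly metrics, joined to arena metadata by position. Flies whose
#' detection or metadata join fails land in a `failures` table; every
#' metadata row appears in exactly one of `metrics` or `failures`.
#'
#' @param frames a [strif_frames()] video or a frame directory path.
#' @param metadata metadata table or CSV path (see [read_metadata()]);
#'   `NULL` synthesises positions `1..n` detected.
#' @param config a [strif_config()].
#' @return A `strif_run` list: `detections`, `traces`, `ethograms`,
#'   `metrics` (one row per fly), `failures`, `flash_frame`, `log`.
#'   If `config$output_dir` is set, tidy CSVs and a resolved-config YAML
#'   are written there.
#' @export
run_strif <- function(frames, metadata = NULL, config) {
  stopifnot(inherits(config, "strif_config"))
  if (is.character(frames)) frames <- read_frames(frames, fps = config$fps)
  log <- list(n_frames = n_frames(frames))
  md <- if (is.null(metadata))
    data.frame(position = seq_len(config$n_expected_flies))
  else read_metadata(metadata)

  det <- detect_flies(frames, min_area = config$min_area,
                      max_area = config$max_area,
                      n_expected = config$n_expected_flies,
                      kernel_radius = config$kernel_radius,
                      polarity = config$polarity,
                      roi_scale = config$roi_scale)
  log$n_detected <- nrow(det)
  log$detection_flagged <- attr(det, "flagged")

  traces <- motion_traces(frames, det, median_window = config$median_window)
  ethograms <- lapply(traces, classify_states,
                      min_immobility = config$min_immobility)
  metrics <- do.call(rbind, Map(function(e, tr) compute_metrics(e, tr),
                                ethograms, traces))
  log$n_epochs <- sum(vapply(ethograms, nrow, 0L))

  # join by arena position = fly_id raster order
  metrics <- merge(md, metrics, by.x = "position", by.y = "fly_id",
                   sort = TRUE)
  matched <- md$position %in% det$fly_id
  failures <- md[!matched, , drop = FALSE]
  if (nrow(failures)) failures$reason <- "not detected"
  log$n_failures <- nrow(failures)

  out <- structure(list(detections = det, traces = traces,
                        ethograms = ethograms, metrics = metrics,
                        failures = failures,
                        flash_frame = traces[[1]]$flash_frame,
                        config = config, log = log),
                   class = "strif_run")
  if (!is.null(config$output_dir)) write_run(out, config$output_dir)
  out
}

write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_detections(run$detections, file.path(dir, "detections.csv"))
  write_traces(run$traces, file.path(dir, "traces.csv"))
  write_ethograms(run$ethograms, file.path(dir, "ethograms.csv"))
  write.csv(run$metrics, file.path(dir, "metrics.csv"), row.names = FALSE)
  if (nrow(run$failures))
    write.csv(run$failures, file.path(dir, "failures.csv"), row.names = FALSE)
  cfg <- run$config
  cfg$output_dir <- NULL
  yaml::write_yaml(unclass(cfg), file.path(dir, "config_resolved.yaml"))
  invisible(dir)
}

#' Run the optogenetic before/after analysis
#'
#' Detects the illumination flash (or takes a supplied onset), splits every
#' fly's ethogram into before/after windows, and computes paired contrasts
#' (after vs before) per genotype for the main struggle parameters, plus
#' unpaired genotype-vs-control contrasts of the per-fly deltas when a
#' control genotype is named.
#'
#' @param frames an RGB [strif_frames()] video or frame directory.
#' @param metadata metadata with a `genotype` column.
#' @param config a [strif_config()].
#' @param flash_time flash onset in seconds; `NULL` detects it from the
#'   video and aborts if none is found.
#' @param control_genotype optional control genotype label for
#'   delta-vs-delta contrasts.
#' @param parameters metric columns contrasted before vs after.
#' @return A `strif_opto` list: the underlying `run`, `flash_time`,
#'   `windowed` (per-fly before/after metric rows), `paired_effects`
#'   (list of `effect_result` per genotype x parameter) and
#'   `delta_effects`.
#' @export
run_optogenetic <- function(frames, metadata, config, flash_time = NULL,
                            control_genotype = NULL,
                            parameters = c("total_active", "ratio",
                                           "strif_speed")) {
  run <- run_strif(frames, metadata, config)
  if (is.null(flash_time)) {
    if (is.null(run$flash_frame))
      stop_param("no flash detected and none supplied")
    flash_time <- (run$flash_frame - 1) / config$fps
  }
  md <- run$metrics
  windowed <- do.call(rbind, Map(function(e, tr) {
    ba <- split_before_after(e, tr, flash_time,
                             min_immobility = config$min_immobility)
    rbind(ba$before, ba$after)
  }, run$ethograms, run$traces))
  windowed <- merge(md[, intersect(c("position", "genotype", "condition"),
                                   names(md)), drop = FALSE],
                    windowed, by.x = "position", by.y = "fly_id")

  genos <- if ("genotype" %in% names(windowed)) unique(windowed$genotype)
           else "all"
  paired_effects <- list(); delta <- list()
  for (g in genos) {
    wg <- if (identical(genos, "all")) windowed
          else windowed[windowed$genotype == g, ]
    for (par in parameters) {
      before <- wg[[par]][wg$window == "before_flash"]
      after <- wg[[par]][wg$window == "after_flash"]
      ok <- is.finite(before) & is.finite(after)
      if (sum(ok) < 5) next
      key <- paste0(g, ":", par)
      paired_effects[[key]] <- effect_contrast(
        after[ok], before[ok], paired = TRUE, label = key,
        n_boot = config$n_boot, n_perm = config$n_perm,
        alpha = config$alpha, seed = config$seed)
      delta[[key]] <- data.frame(genotype = g, parameter = par,
                                 delta = after[ok] - before[ok])
    }
  }
  delta_effects <- list()
  if (!is.null(control_genotype)) {
    dd <- do.call(rbind, delta)
    for (par in parameters) {
      ctrl <- dd$delta[dd$genotype == control_genotype & dd$parameter == par]
      for (g in setdiff(genos, control_genotype)) {
        ex <- dd$delta[dd$genotype == g & dd$parameter == par]
        if (length(ex) < 5 || length(ctrl) < 5) next
        key <- paste0(g, ":", par)
        delta_effects[[key]] <- effect_contrast(
          ex, ctrl, paired = FALSE, label = key, n_boot = config$n_boot,
          n_perm = config$n_perm, alpha = config$alpha,
          seed = config$seed)
      }
    }
  }
  structure(list(run = run, flash_time = flash_time, windowed = windowed,
                 paired_effects = paired_effects,
                 delta_effects = delta_effects),
            class = "strif_opto")
}
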