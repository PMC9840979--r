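# figure helpers (ggplot2): ethogram rasters, effect-size heatmaps,
# paired mean-difference panels

#' Raster plot of ethograms
#'
#' One row per fly; active epochs drawn as filled bars. With `align_at`,
#' times are shifted so the flash onset sits at 0 s (event-aligned view).
#'
#' @param ethograms list of `strif_ethogram`s.
#' @param align_at optional alignment time in seconds (e.g. flash onset).
#' @return A ggplot object.
#' @export
plot_ethogram_raster <- function(ethograms, align_at = 0) {
  if (inherits(ethograms, "strif_ethogram")) ethograms <- list(ethograms)
  df <- do.call(rbind, lapply(ethograms, function(e)
    cbind(fly = factor(attr(e, "fly_id")), as.data.frame(e))))
  df$start <- df$start - align_at
  df$end <- df$end - align_at
  df <- df[df$state == "active", ]
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = start, xmax = end,
      ymin = as.integer(fly) - 0.4,
      ymax = as.integer(fly) + 0.4), fill = "black") +
    ggplot2::geom_vline(xintercept = 0, colour = "red",
                        linetype = if (align_at > 0) "solid" else "blank") +
    ggplot2::scale_y_continuous(breaks = seq_along(ethograms),
                                labels = levels(df$fly)) +
    ggplot2::labs(x = "time (s)", y = "fly", title = "activity raster") +
    ggplot2::theme_minimal()
}

#' Heatmap of an effect-size matrix
#'
#' Cohen's d per (intervention, parameter) cell, asterisked where the
#' permutation p is below the matrix threshold.
#'
#' @param em an [effect_matrix()].
#' @return A ggplot object.
#' @export
plot_effect_matrix <- function(em) {
  stopifnot(inherits(em, "effect_matrix"))
  df <- expand.grid(intervention = rownames(em$d),
                    parameter = colnames(em$d), stringsAsFactors = FALSE)
  df$d <- as.vector(em$d)
  df$star <- ifelse(as.vector(em$stars), "*", "")
  ggplot2::ggplot(df, ggplot2::aes(parameter, intervention,
                                   fill = d)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(d), "",
                     sprintf("%.2f%s", d, star)))) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", na.value = "grey90") +
    ggplot2::labs(fill = "Cohen's d") +
    ggplot2::theme_minimal()
}

#' Paired before/after panel with bootstrap mean-difference distribution
#'
#' Gardner-Altman style estimation plot for a paired contrast: the paired
#' observations as connected points, beside the bootstrap distribution of
#' the mean difference with its 95% CI bar.
#'
#' @param before,after paired samples.
#' @param n_boot bootstrap resamples for the difference distribution.
#' @param seed integer seed.
#' @return A ggplot object.
#' @export
plot_paired_effect <- function(before, after, n_boot = 5000, seed = 1L) {
  stopifnot(length(before) == length(after))
  d <- after - before
  boots <- with_seed(seed, {
    ix <- matrix(sample.int(length(d), length(d) * n_boot, TRUE),
                 ncol = n_boot)
    colMeans(matrix(d[ix], nrow = length(d)))
  })
  ci <- bca_ci(d, n_boot = n_boot, seed = seed)
  pts <- data.frame(id = rep(seq_along(d), 2),
                    phase = rep(c("before", "after"), each = length(d)),
                    value = c(before, after))
  pts$phase <- factor(pts$phase, levels = c("before", "after"))
  p1 <- ggplot2::ggplot(pts, ggplot2::aes(phase, value,
                                          group = id)) +
    ggplot2::geom_line(alpha = 0.4) + ggplot2::geom_point() +
    ggplot2::theme_minimal()
  p2 <- ggplot2::ggplot(data.frame(boot = boots), ggplot2::aes(boot)) +
    ggplot2::geom_density(fill = "grey70") +
    ggplot2::geom_vline(xintercept = mean(d)) +
    ggplot2::annotate("segment", x = ci[1], xend = ci[2], y = 0, yend = 0,
                      linewidth = 2) +
    ggplot2::labs(x = "mean difference (after - before)") +
    ggplot2::theme_minimal()
  list(pairs = p1, difference = p2)
}

#' Plot a pooled epoch-duration histogram
#'
#' @param hist output of [duration_histogram()].
#' @return A ggplot object.
#' @export
plot_duration_histogram <- function(hist) {
  ggplot2::ggplot(hist, ggplot2::aes(bin_lo + (bin_hi - bin_lo) / 2,
                                     prob, fill = state)) +
    ggplot2::geom_col(position = "dodge",
                      width = (hist$bin_hi - hist$bin_lo)[1] * 0.9) +
    ggplot2::geom_vline(xintercept = 5, linetype = "dashed") +
    ggplot2::labs(x = "epoch duration (s)", y = "probability") +
    ggplot2::theme_minimal()
}

utils::globalVariables(c("start", "end", "fly", "parameter", "intervention",
                         "d", "star", "phase", "value", "id", "boot",
                         "bin_lo", "bin_hi", "prob", "state"))
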