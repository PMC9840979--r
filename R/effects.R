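# effect-size matrix assembly and cross-paradigm delta regression

#' Assemble an effect-size matrix with significance marks
#'
#' Arranges Cohen's d values of many contrasts into an
#' intervention-by-parameter matrix with an asterisk mask at p < 0.05, the
#' layout used for heatmap panels comparing interventions across struggle
#' and walking parameters.
#'
#' @param results either a data frame with columns `intervention`,
#'   `parameter`, `d`, `p`, or a list of [effect_contrast()] results whose
#'   labels are `"intervention:parameter"`.
#' @param p_threshold asterisk threshold.
#' @return An `effect_matrix` list: `d` (numeric matrix), `p`, `stars`
#'   (logical), `missing` (logical mask of absent cells).
#' @export
effect_matrix <- function(results, p_threshold = 0.05) {
  if (!is.data.frame(results)) {
    stopifnot(length(results) >= 1)
    results <- do.call(rbind, lapply(results, function(r) {
      key <- strsplit(r$label, ":", fixed = TRUE)[[1]]
      if (length(key) != 2)
        stop_param("labels must be 'intervention:parameter', got '%s'", r$label)
      data.frame(intervention = key[1], parameter = key[2],
                 d = r$cohens_d, p = r$p_permutation)
    }))
  }
  stopifnot(nrow(results) >= 1,
            all(c("intervention", "parameter", "d", "p") %in% names(results)))
  key <- paste(results$intervention, results$parameter, sep = "\r")
  if (anyDuplicated(key))
    stop_param("duplicate (intervention, parameter) keys")
  rows <- unique(results$intervention)
  cols <- unique(results$parameter)
  dm <- matrix(NA_real_, length(rows), length(cols),
               dimnames = list(rows, cols))
  pm <- dm
  dm[cbind(match(results$intervention, rows),
           match(results$parameter, cols))] <- results$d
  pm[cbind(match(results$intervention, rows),
           match(results$parameter, cols))] <- results$p
  structure(list(d = dm, p = pm,
                 stars = !is.na(pm) & pm < p_threshold,
                 missing = is.na(dm)),
            class = "effect_matrix")
}

#' @export
print.effect_matrix <- function(x, ...) {
  cat("<effect_matrix> Cohen's d (",
      nrow(x$d), "interventions x", ncol(x$d), "parameters ), * p <0.05\n")
  shown <- matrix(sprintf("%.2f%s", x$d, ifelse(x$stars, "*", "")),
                  nrow(x$d), dimnames = dimnames(x$d))
  shown[x$missing] <- "."
  print(shown, quote = FALSE)
  invisible(x)
}

#' Cross-paradigm delta regression
#'
#' Ordinary least squares of per-manipulation y-deltas on x-deltas,
#' reporting the adjusted R-squared
#' `1 - (1 - R^2) * (n - 1) / (n - 2)` and the two-sided slope p from the
#' t distribution. Used to ask whether changes in one paradigm (e.g.
#' walking activity:inactivity ratio) predict changes in another (e.g.
#' struggle ratio).
#'
#' @param x,y paired delta values, one per manipulation (n >= 3).
#' @param x_label,y_label axis labels stored in the result.
#' @return A `delta_regression` list: `slope`, `intercept`, `r2_adj`,
#'   `p_slope`, `n_points`, labels and the underlying `lm` fit.
#' @export
delta_regression <- function(x, y, x_label = "x", y_label = "y") {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop_param("need at least 3 manipulations")
  if (var(x) == 0) stop_param("zero variance in x: slope undefined")
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # collinear input warns but is valid
  n <- length(x)
  r2 <- sm$r.squared
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r2_adj = 1 - (1 - r2) * (n - 1) / (n - 2),
                 p_slope = unname(sm$coefficients[2, 4]),
                 n_points = n, x_label = x_label, y_label = y_label,
                 fit = fit),
            class = "delta_regression")
}

#' @export
print.delta_regression <- function(x, ...) {
  cat(sprintf("<delta_regression> %s ~ %s (n = %d)\n",
              x$y_label, x$x_label, x$n_points))
  cat(sprintf("  slope = %.4g, intercept = %.4g, R2adj = %.3g, p = %.3g\n",
              x$slope, x$intercept, x$r2_adj, x$p_slope))
  invisible(x)
}

#' Tiered significance stars
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, else `""`.
#'
#' @param p p-value vector.
#' @return Character vector of star annotations.
#' @export
p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}
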