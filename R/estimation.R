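# estimation statistics: standardized effect sizes, BCa bootstrap CIs,
# permutation t-tests, analytic power

#' Glass delta
#'
#' Mean difference (experiment minus control) standardized by the sample
#' standard deviation of the control group (n-1 denominator).
#'
#' @param experiment,control numeric vectors.
#' @return Scalar delta.
#' @export
glass_delta <- function(experiment, control) {
  if (length(control) < 2) stop_param("need at least 2 control values")
  s <- sd(control)
  if (s == 0) stop_param("zero control SD: Glass delta undefined")
  (mean(experiment) - mean(control)) / s
}

#' Cohen's d
#'
#' Unpaired: mean difference (experiment minus control) over the pooled SD
#' with n-1 weights. Paired: mean within-pair difference over the SD of the
#' differences (default) or over the average of the two group SDs
#' (`standardizer = "average"`).
#'
#' @param experiment,control numeric vectors; equal length when paired.
#' @param paired paired-samples variant.
#' @param standardizer paired-only: `"difference"` (SD of pair differences)
#'   or `"average"` (mean of the two SDs).
#' @return Scalar d.
#' @export
cohens_d <- function(experiment, control, paired = FALSE,
                     standardizer = c("difference", "average")) {
  standardizer <- match.arg(standardizer)
  na <- length(experiment); nb <- length(control)
  if (paired) {
    if (na != nb) stop_param("paired samples must have equal length")
    if (na < 2) stop_param("need at least 2 pairs")
    d <- experiment - control
    s <- if (standardizer == "difference") sd(d)
         else (sd(experiment) + sd(control)) / 2
    if (s == 0) stop_param("zero standardizer SD")
    return(mean(d) / s)
  }
  if (na < 2 || nb < 2) stop_param("need at least 2 values per group")
  sp <- sqrt(((na - 1) * var(experiment) + (nb - 1) * var(control)) /
             (na + nb - 2))
  if (sp == 0) stop_param("zero pooled SD")
  (mean(experiment) - mean(control)) / sp
}

#' Effect-magnitude interpretation band
#'
#' Standard interpretation cuts on the absolute standardized effect:
#' negligible < 0.2 <= small < 0.5 <= moderate < 0.8 <= large.
#'
#' @param x standardized effect size(s).
#' @return Character vector of band labels.
#' @export
magnitude_band <- function(x) {
  cut(abs(x), c(-Inf, 0.2, 0.5, 0.8, Inf),
      labels = c("negligible", "small", "moderate", "large"),
      right = FALSE) |> as.character()
}

#' BCa bootstrap confidence interval
#'
#' Bias-corrected and accelerated interval for `statistic(x)` (one sample)
#' or `statistic(x, y)` (two independent samples, resampled independently).
#' Bias correction comes from the fraction of the bootstrap distribution
#' below the point estimate; acceleration from jackknife skewness. Falls
#' back to the percentile interval with a warning when the bootstrap
#' distribution degenerates.
#'
#' @param x numeric sample (for paired designs, pass the pair differences).
#' @param y optional second sample for two-sample statistics.
#' @param statistic function of one (or two) samples; default mean
#'   (or mean difference `x - y`).
#' @param n_boot number of bootstrap resamples (>= 1000).
#' @param alpha two-sided miss probability; 0.05 gives a 95% CI.
#' @param seed integer seed; the interval is reproducible given the seed.
#' @return Length-2 vector `(low, high)` with attributes `estimate` and
#'   `method` (`"bca"` or `"percentile"`).
#' @export
bca_ci <- function(x, y = NULL, statistic = NULL, n_boot = 5000,
                   alpha = 0.05, seed = NULL) {
  if (length(x) < 5) stop_param("need n >= 5 for a bootstrap CI")
  if (n_boot < 1000) stop_param("n_boot must be >= 1000")
  two <- !is.null(y)
  if (is.null(statistic))
    statistic <- if (two) function(a, b) mean(a) - mean(b) else mean
  est <- if (two) statistic(x, y) else statistic(x)
  boots <- with_seed(seed, {
    if (two) {
      ix <- matrix(sample.int(length(x), length(x) * n_boot, TRUE), ncol = n_boot)
      iy <- matrix(sample.int(length(y), length(y) * n_boot, TRUE), ncol = n_boot)
      vapply(seq_len(n_boot),
             function(b) statistic(x[ix[, b]], y[iy[, b]]), 0)
    } else {
      ix <- matrix(sample.int(length(x), length(x) * n_boot, TRUE), ncol = n_boot)
      vapply(seq_len(n_boot), function(b) statistic(x[ix[, b]]), 0)
    }
  })
  perc <- function() {
    ci <- quantile(boots, c(alpha / 2, 1 - alpha / 2), names = FALSE)
    structure(ci, estimate = est, method = "percentile")
  }
  prop_below <- mean(boots < est)
  if (prop_below == 0 || prop_below == 1) {
    warning("degenerate bootstrap distribution; falling back to percentile")
    return(perc())
  }
  z0 <- qnorm(prop_below)
  # jackknife over every observation (both groups for two-sample)
  jack <- if (two) {
    c(vapply(seq_along(x), function(i) statistic(x[-i], y), 0),
      vapply(seq_along(y), function(i) statistic(x, y[-i]), 0))
  } else {
    vapply(seq_along(x), function(i) statistic(x[-i]), 0)
  }
  u <- mean(jack) - jack
  denom <- sum(u^2)^1.5
  a <- if (denom == 0) 0 else sum(u^3) / (6 * denom)
  zl <- qnorm(alpha / 2); zu <- qnorm(1 - alpha / 2)
  a1 <- pnorm(z0 + (z0 + zl) / (1 - a * (z0 + zl)))
  a2 <- pnorm(z0 + (z0 + zu) / (1 - a * (z0 + zu)))
  ci <- quantile(boots, c(a1, a2), names = FALSE)
  structure(ci, estimate = est, method = "bca")
}

#' Two-sided permutation t-test
#'
#' p = proportion of arrangements (group-label shuffles, or sign flips for
#' paired data) whose absolute mean difference is at least the observed
#' one. The identity arrangement is always counted, so p > 0. Exact
#' enumeration is used automatically when the total number of arrangements
#' is at most `exact_limit`; otherwise `n_perm` random arrangements are
#' drawn and the identity is added to numerator and denominator.
#'
#' @param a,b numeric samples; equal length when paired.
#' @param paired sign-flip test on `a - b` instead of label shuffling.
#' @param n_perm number of sampled arrangements (>= 1000) when not exact.
#' @param seed integer seed for the sampled mode.
#' @param exact force (`TRUE`)/forbid (`FALSE`) enumeration; `NULL` = auto.
#' @param exact_limit arrangement-count cutoff for automatic enumeration.
#' @return p-value with attributes `n_arrangements` and `exact`.
#' @export
permutation_test <- function(a, b, paired = FALSE, n_perm = 10000,
                             seed = NULL, exact = NULL,
                             exact_limit = 20000) {
  if (length(a) == 0 || length(b) == 0) stop_param("empty group")
  eps <- 1e-12
  if (paired) {
    if (length(a) != length(b)) stop_param("paired samples must match")
    d <- a - b
    n <- length(d)
    obs <- abs(mean(d))
    tol <- eps * max(1, obs, mean(abs(d)))
    do_exact <- exact %||% (2^n <= exact_limit)
    if (do_exact) {
      total <- 2^n
      signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
      means <- abs(as.vector(signs %*% d) / n)
      p <- sum(means >= obs - tol) / total
      return(structure(p, n_arrangements = total, exact = TRUE))
    }
    if (n_perm < 1000) stop_param("n_perm must be >= 1000")
    means <- with_seed(seed, {
      s <- matrix(sample(c(-1, 1), n * n_perm, TRUE), nrow = n)
      abs(colSums(s * d) / n)
    })
    p <- (1 + sum(means >= obs - tol)) / (n_perm + 1)
    return(structure(p, n_arrangements = n_perm + 1, exact = FALSE))
  }
  z <- c(a, b)
  na <- length(a); n <- length(z)
  obs <- abs(mean(a) - mean(b))
  tol <- eps * max(1, obs, mean(abs(z)))
  do_exact <- exact %||% (choose(n, na) <= exact_limit)
  tot_sum <- sum(z)
  diff_from_sa <- function(sa) abs(sa / na - (tot_sum - sa) / (n - na))
  if (do_exact) {
    cmb <- combn(n, na)
    sa <- colSums(matrix(z[cmb], nrow = na))
    p <- sum(diff_from_sa(sa) >= obs - tol) / ncol(cmb)
    return(structure(p, n_arrangements = ncol(cmb), exact = TRUE))
  }
  if (n_perm < 1000) stop_param("n_perm must be >= 1000")
  cnt <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      sa <- sum(z[sample.int(n, na)])
      diff_from_sa(sa) >= obs - tol
    }, NA))
  })
  p <- (1 + cnt) / (n_perm + 1)
  structure(p, n_arrangements = n_perm + 1, exact = FALSE)
}

#' Full estimation contrast between two groups
#'
#' Bundles the estimation-statistics layer for one contrast: mean
#' difference (experiment minus control), Glass delta, Cohen's d, BCa 95%
#' CI of the mean difference, two-sided permutation p and the magnitude
#' interpretation band.
#'
#' @param experiment,control numeric samples (before/after values of the
#'   same flies when `paired = TRUE`, with `control` = before).
#' @param paired paired design.
#' @param label contrast label.
#' @param n_boot,n_perm,alpha resampling parameters.
#' @param seed integer seed recorded in the result.
#' @return An `effect_result` list.
#' @export
effect_contrast <- function(experiment, control, paired = FALSE,
                            label = "contrast", n_boot = 5000,
                            n_perm = 10000, alpha = 0.05, seed = 1L) {
  md <- mean(experiment) - mean(control)
  d <- cohens_d(experiment, control, paired = paired)
  gd <- tryCatch(glass_delta(experiment, control), error = function(e) NA_real_)
  ci <- if (paired) bca_ci(experiment - control, n_boot = n_boot,
                           alpha = alpha, seed = seed)
        else bca_ci(experiment, control, n_boot = n_boot, alpha = alpha,
                    seed = seed)
  p <- permutation_test(experiment, control, paired = paired,
                        n_perm = n_perm, seed = seed + 1L)
  structure(list(label = label, paired = paired,
                 n_exp = length(experiment), n_ctrl = length(control),
                 mean_difference = md, glass_delta = gd, cohens_d = d,
                 ci95 = as.numeric(ci), ci_method = attr(ci, "method"),
                 p_permutation = as.numeric(p),
                 p_exact = attr(p, "exact"),
                 magnitude_band = magnitude_band(d),
                 alpha = alpha, seed = seed),
            class = "effect_result")
}

#' @export
print.effect_result <- function(x, ...) {
  cat(sprintf("<effect_result> %s%s\n", x$label,
              if (x$paired) " (paired)" else ""))
  cat(sprintf("  n = %d vs %d; mean diff = %.4g [95CI %.4g, %.4g]\n",
              x$n_exp, x$n_ctrl, x$mean_difference, x$ci95[1], x$ci95[2]))
  cat(sprintf("  Glass delta = %.3g, Cohen's d = %.3g (%s), p_perm = %.4g\n",
              x$glass_delta, x$cohens_d, x$magnitude_band, x$p_permutation))
  invisible(x)
}

#' Analytic power of the two-sided two-sample t-test
#'
#' Power via the noncentral t distribution with noncentrality
#' `d * sqrt(n/2)` and `2n - 2` degrees of freedom, `n` per group.
#'
#' @param n_per_group per-group sample size (>= 2).
#' @param d true standardized effect size (>= 0).
#' @param alpha two-sided significance level.
#' @return Power in `[0, 1]` (equals `alpha` at `d = 0`).
#' @export
power_ttest <- function(n_per_group, d, alpha = 0.05) {
  stopifnot(n_per_group >= 2, d >= 0, alpha > 0, alpha < 1)
  df <- 2 * n_per_group - 2
  ncp <- d * sqrt(n_per_group / 2)
  tc <- qt(1 - alpha / 2, df)
  1 - pt(tc, df, ncp = ncp) + pt(-tc, df, ncp = ncp)
}
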