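# activity/immobility segmentation under the 5-second rule, metrics,
# before/after splitting, duration histograms

test_that("an all-zero trace is one inactive epoch spanning the assay", {
  eth <- classify_states(rep(0, 2999), fps = 10)
  expect_equal(nrow(eth), 1)
  expect_equal(eth$state, "inactive")
  expect_equal(c(eth$start, eth$end), c(0, 300))
  expect_error(classify_states(numeric(0), fps = 10), "empty")
})

test_that("a quiescent gap under five seconds is absorbed into activity", {
  # active 10 s, quiet 4 s, active 10 s at 10 fps
  x <- c(rep(8, 100), rep(0, 40), rep(8, 99))
  eth <- classify_states(x, fps = 10)
  expect_equal(nrow(eth), 1)
  expect_equal(eth$state, "active")
  # the same gap at 5 s is immobility
  x2 <- c(rep(8, 100), rep(0, 50), rep(8, 89))
  eth2 <- classify_states(x2, fps = 10)
  expect_equal(eth2$state, c("active", "inactive", "active"))
})

test_that("programmed epoch boundaries are recovered within one second", {
  p <- behavior_program(c("active", "inactive", "active"), c(30, 20, 10))
  eth <- classify_states(indicator_trace(p, 30), fps = 30)
  truth <- program_to_ethogram(p)
  cmp <- compare_to_truth(eth, truth, tol = 1)
  expect_equal(cmp$n_matched, cmp$n_boundaries)
  expect_true(cmp$state_sequence_equal)
})

test_that("ethogram invariants hold over random traces (tiling, alternation, 5-s rule)", {
  for (s in 1:50) {
    p <- sample_program(120, 10, 7, seed = 700 + s)
    eth <- classify_states(indicator_trace(p, 10), fps = 10)
    expect_equal(eth$start[1], 0)
    expect_equal(eth$end[nrow(eth)], 120)
    if (nrow(eth) > 1) {
      expect_equal(eth$start[-1], eth$end[-nrow(eth)])  # no gaps/overlap
      expect_true(all(eth$state[-1] != eth$state[-nrow(eth)]))
    }
    ina <- eth$state == "inactive"
    expect_true(all(eth$end[ina] - eth$start[ina] >= 5 - 1e-9))
  }
})

test_that("segmentation is idempotent on its own induced binary trace", {
  for (s in 1:10) {
    p <- sample_program(60, 8, 7, seed = 800 + s)
    eth <- classify_states(indicator_trace(p, 10), fps = 10)
    induced <- numeric(599)
    t0 <- (seq_len(599) - 1) / 10
    for (i in seq_len(nrow(eth)))
      if (eth$state[i] == "active")
        induced[t0 >= eth$start[i] - 1e-9 & t0 < eth$end[i] - 1e-9] <- 1
    eth2 <- classify_states(induced, fps = 10)
    expect_equal(eth2$state, eth$state)
    expect_equal(eth2$start, eth$start, tolerance = 1e-9)
  }
})

test_that("metrics arithmetic: totals, ratio, counts, conservation", {
  p <- behavior_program(c("active", "inactive"), c(200, 100))
  eth <- classify_states(indicator_trace(p, 10), fps = 10)
  m <- compute_metrics(eth)
  expect_equal(m$ratio, 2.0, tolerance = 0.01)
  expect_equal(m$total_active + m$total_inactive, 300)
  expect_equal(m$n_active_epochs, 1)
  expect_equal(m$n_inactive_epochs, 1)
  expect_equal(m$mean_active_duration * m$n_active_epochs, m$total_active)
  expect_lte(abs(m$n_active_epochs - m$n_inactive_epochs), 1)
  expect_error(compute_metrics(eth, window = c(10, 10)), "window")
})

test_that("a fully active window flags the ratio as undefined", {
  eth <- classify_states(rep(8, 299), fps = 10)
  m <- compute_metrics(eth)
  expect_false(m$ratio_defined)
  expect_true(is.na(m$ratio))
})

test_that("time conservation is exact for arbitrary windows", {
  for (s in 1:10) {
    p <- sample_program(100, 9, 8, seed = 900 + s)
    eth <- classify_states(indicator_trace(p, 10), fps = 10)
    for (w in list(c(0, 100), c(13.7, 55.2), c(0.1, 99.9))) {
      m <- compute_metrics(eth, window = w)
      expect_identical(m$total_active + m$total_inactive, w[2] - w[1])
    }
  }
})

test_that("programmed mean activity ratio is recovered across a fixture batch", {
  true_r <- c(); got_r <- c()
  for (s in 1:100) {
    p <- sample_program(300, 20, 10, seed = 1000 + s)
    truth <- program_to_ethogram(p)
    tm <- compute_metrics(truth)
    eth <- classify_states(indicator_trace(p, 10), fps = 10)
    m <- compute_metrics(eth)
    if (tm$ratio_defined && m$ratio_defined) {
      true_r <- c(true_r, tm$ratio); got_r <- c(got_r, m$ratio)
    }
  }
  sem <- sd(got_r - true_r) / sqrt(length(got_r))
  expect_lt(abs(mean(got_r) - mean(true_r)), max(2 * sem, 0.01))
})

test_that("splitting at the flash yields two exact windows and re-applies the 5-s rule", {
  # inactive epoch straddles the flash; its 3-s post-flash fragment is
  # not immobility and must be absorbed into the following activity
  p <- behavior_program(c("active", "inactive", "active"), c(27, 8, 25))
  eth <- classify_states(indicator_trace(p, 10), fps = 10)
  ba <- split_before_after(eth, flash_time = 32)
  expect_equal(ba$before$window_end - ba$before$window_start, 32)
  expect_equal(ba$after$window_end - ba$after$window_start, 28)
  expect_equal(ba$before$total_active + ba$before$total_inactive, 32)
  after_eth <- attr(ba, "after_ethogram")
  expect_equal(after_eth$state[1], "active")  # fragment absorbed
  expect_equal(ba$after$total_active, 28)
  expect_error(split_before_after(eth, flash_time = 0), "degenerate")
  expect_error(split_before_after(eth, flash_time = 60), "degenerate")
})

test_that("a symmetric program gives matched before/after metrics", {
  half <- list(state = c("active", "inactive"), d = c(10, 20))
  p <- behavior_program(c(half$state, half$state), c(half$d, half$d))
  eth <- classify_states(indicator_trace(p, 10), fps = 10)
  ba <- split_before_after(eth, flash_time = 30)
  expect_equal(ba$before$total_active, ba$after$total_active, tolerance = 0.2)
  expect_equal(ba$before$n_active_epochs, ba$after$n_active_epochs)
})

test_that("post-flash activity suppression lowers the after-window ratio in every fly", {
  for (s in 1:5) {
    pre <- sample_program(30, 8, 6, seed = 1100 + s)
    last <- nrow(pre)
    p <- if (pre$state[last] == "inactive")
      behavior_program(pre$state, c(pre$duration[-last],
                                    pre$duration[last] + 30))
    else behavior_program(c(pre$state, "inactive"), c(pre$duration, 30))
    eth <- classify_states(indicator_trace(p, 10), fps = 10)
    ba <- split_before_after(eth, flash_time = 30)
    b <- if (ba$before$ratio_defined) ba$before$ratio else Inf
    a <- if (ba$after$ratio_defined) ba$after$ratio else Inf
    expect_lt(a, b)
  }
})

test_that("duration histograms are normalized with half-open 5-s bins", {
  p <- behavior_program("inactive", 300)
  eth <- program_to_ethogram(p)
  h <- duration_histogram(eth)
  expect_equal(sum(h$prob), 1)
  expect_equal(h$prob[h$bin_lo == 300], 1)  # [300, 305) holds the epoch
  # exponential active durations recover the binned distribution
  durs <- c()
  for (s in 1:60) {
    p <- sample_program(300, 20, 10, seed = 1200 + s)
    keep <- seq_len(max(nrow(p) - 1, 1))
    durs <- c(durs, p$duration[keep][p$state[keep] == "active"])
  }
  ad <- durs[seq_len(min(1000, length(durs)))]
  # build an ethogram-like pooled histogram straight from durations
  brks <- seq(0, ceiling(max(ad) / 5) * 5, by = 5)
  obs <- table(cut(ad, brks, right = FALSE))
  # truncated-exponential bin probabilities (shifted exp, floor 1, mean 20)
  pexp_shift <- function(x) ifelse(x <= 1, 0, 1 - exp(-(x - 1) / 19))
  pr <- diff(pexp_shift(brks)); pr <- pr / sum(pr)
  keep <- pr > 1e-6
  chi <- suppressWarnings(chisq.test(as.vector(obs)[keep], p = pr[keep],
                                     rescale.p = TRUE))
  expect_gt(chi$p.value, 0.001)
})

test_that("bare-series classification requires fps and keeps assay duration", {
  expect_error(classify_states(rep(0, 10)), "fps")
  eth <- classify_states(rep(0, 10), fps = 2)
  expect_equal(attr(eth, "assay_duration"), 5.5)
})
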