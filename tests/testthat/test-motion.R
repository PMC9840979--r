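# frame-differencing motion traces, denoising, struggle speed, flash

test_that("a static video has an exactly zero trace of the contracted length", {
  f <- disk_frame(40, 40, rbind(c(20, 20)))
  v <- frames_from_list(rep(list(f), 10), fps = 10)
  tr <- frame_difference_trace(v, list(top = 10, left = 10, side = 21))
  expect_length(tr, 9)
  expect_true(all(tr == 0))
  expect_error(frame_difference_trace(frames_from_list(list(f))), "frames")
})

test_that("a displaced disk's trace equals the symmetric-difference oracle", {
  h <- 50; w <- 50; r <- 5; d <- 3
  f1 <- disk_frame(h, w, rbind(c(25, 25)), radius = r)
  f2 <- disk_frame(h, w, rbind(c(25, 25 + d)), radius = r)
  v <- frames_from_list(list(f1, f2), fps = 10)
  roi <- list(top = 10, left = 10, side = 31)
  got <- frame_difference_trace(v, roi)
  # oracle: enumerate disk pixel sets; only the symmetric difference
  # contributes, each at the fly/background contrast
  p1 <- disk_pixels(h, c(25, 25), r)
  p2 <- disk_pixels(h, c(25, 25 + d), r)
  symdiff <- length(setdiff(p1, p2)) + length(setdiff(p2, p1))
  expect_equal(got, symdiff * (200 - 30) / 31^2)
})

test_that("motion energy grows with programmed jitter amplitude", {
  means <- vapply(c(1, 2, 4), function(a) {
    p <- behavior_program("active", 10, amplitude = a)
    spec <- render_spec(frame_size = c(60, 60), fps = 10, n_flies = 1,
                        fly_radius = 5, seed = 12)
    rv <- render_video(p, spec)
    mean(frame_difference_trace(rv$frames, list(top = 15, left = 15, side = 31)))
  }, 0)
  expect_true(all(diff(means) > 0))
})

test_that("the median filter removes isolated spikes and keeps zeros at zero", {
  expect_equal(denoise_trace(rep(0, 50), 5), rep(0, 50))
  x <- rep(0, 50); x[25] <- 9
  expect_equal(denoise_trace(x, 5), rep(0, 50))
  expect_error(denoise_trace(x, 4), "odd")
})

test_that("the minimum-difference floor zeroes sub-floor values only", {
  x <- c(0.5, 3, 0.4, 5, 1)
  y <- denoise_trace(x, 3, min_diff_floor = 1)
  expect_true(all(y[y > 0] > 1))
})

test_that("a noisy static fly denoises to an identically zero activity trace", {
  p <- behavior_program("inactive", 20)
  spec <- render_spec(frame_size = c(80, 100), fps = 10, n_flies = 1,
                      noise_fraction = 0.01, seed = 21)
  rv <- render_video(p, spec)
  det <- detect_flies(rv$frames, n_expected = 1)
  tr <- motion_traces(rv$frames, det)[[1]]
  expect_true(all(tr$activity == 0))
  expect_gt(tr$floor, 0)
})

test_that("motion trace contracts hold on a noisy multi-fly fixture", {
  rv <- render_fixture(n_flies = 2, duration = 10, fps = 10,
                       noise = 0.01, seed = 31)
  det <- detect_flies(rv$frames, n_expected = 2)
  trs <- motion_traces(rv$frames, det)
  for (tr in trs) {
    expect_length(tr$activity, n_frames(rv$frames) - 1)
    expect_true(all(tr$activity >= 0))
    expect_true(all(tr$background >= 0))
  }
})

test_that("stride-2 differencing is blind to period-2 oscillation", {
  # blob alternates between two positions every frame: consecutive frames
  # always differ, alternating frames never do
  f1 <- disk_frame(40, 60, rbind(c(20, 25)))
  f2 <- disk_frame(40, 60, rbind(c(20, 30)))
  v <- frames_from_list(rep(list(f1, f2), 10), fps = 10)
  roi <- list(top = 5, left = 10, side = 31)
  expect_true(all(frame_difference_trace(v, roi, stride = 1) > 0))
  expect_true(all(frame_difference_trace(v, roi, stride = 2) == 0))
})

test_that("strif_speed averages over active epochs and flags an all-inactive fly", {
  rv <- render_fixture(n_flies = 1, duration = 20, fps = 10,
                       mean_active = 6, mean_inactive = 8, seed = 41)
  det <- detect_flies(rv$frames, n_expected = 1)
  tr <- motion_traces(rv$frames, det)[[1]]
  eth <- classify_states(tr)
  sp <- strif_speed(tr, eth)
  expect_gt(sp, 0)
  # all-inactive: speed 0 with the no-activity flag
  p <- behavior_program("inactive", 10)
  spec <- render_spec(frame_size = c(40, 40), fps = 10, n_flies = 1, seed = 2)
  rv0 <- render_video(p, spec)
  det0 <- detect_flies(rv0$frames, n_expected = 1)
  tr0 <- motion_traces(rv0$frames, det0)[[1]]
  eth0 <- classify_states(tr0)
  sp0 <- strif_speed(tr0, eth0)
  expect_equal(as.numeric(sp0), 0)
  expect_true(attr(sp0, "no_activity"))
})

test_that("struggle speed increases strictly with flailing amplitude", {
  # the ROI must cover the full excursion range (radius + max amplitude),
  # otherwise large jumps leave the region and the statistic saturates
  roi <- list(top = 40 - 13, left = 40 - 13, side = 27)
  for (s in 13:15) {
    speeds <- vapply(c(1, 2, 4, 8), function(a) {
      p <- behavior_program("active", 10, amplitude = a)
      spec <- render_spec(frame_size = c(80, 80), fps = 10, n_flies = 1,
                          fly_radius = 5, seed = s)
      rv <- render_video(p, spec)
      eth <- classify_states(
        denoise_trace(frame_difference_trace(rv$frames, roi), 5, 0),
        fps = 10)
      strif_speed(rv$frames, eth, roi = roi)
    }, 0)
    expect_true(all(diff(speeds) > 0))
  }
})

test_that("flash detection finds the onset within one frame, or none without flash", {
  rv0 <- render_fixture(n_flies = 1, duration = 5, fps = 10, seed = 3)
  v0 <- strif_frames(rbind(rv0$frames$pix, rv0$frames$pix, rv0$frames$pix),
                     rv0$frames$h, rv0$frames$w, 3L, 10)  # fake RGB, no flash
  expect_null(detect_flash(v0))
  for (s in 1:20) {
    ff <- 20 + s
    p <- sample_program(8, 3, 3, amplitude = 2, seed = s)
    spec <- render_spec(frame_size = c(50, 60), fps = 10, n_flies = 1,
                        flash_frame = ff, flash_shift = c(30, 0, 0),
                        seed = s)
    rv <- render_video(p, spec)
    fl <- detect_flash(rv$frames)
    expect_false(is.null(fl))
    expect_lte(abs(fl$frame - ff), 1)
  }
})

test_that("a five-minute-off protocol has its onset detected at 300 s", {
  p <- sample_program(600, 30, 20, amplitude = 2, seed = 5)
  fps <- 2
  spec <- render_spec(frame_size = c(50, 60), fps = fps, n_flies = 1,
                      flash_frame = 300 * fps + 1, seed = 5)
  rv <- render_video(p, spec)
  fl <- detect_flash(rv$frames)
  expect_equal(fl$frame, 300 * fps + 1)
})

test_that("trace CSV export writes one row per frame per fly plus a flash table", {
  p <- sample_program(6, 3, 3, seed = 8)
  spec <- render_spec(frame_size = c(50, 60), fps = 10, n_flies = 1,
                      flash_frame = 31, seed = 8)
  rv <- render_video(p, spec)
  det <- detect_flies(rv$frames, n_expected = 1)
  trs <- motion_traces(rv$frames, det)
  d <- withr::local_tempdir()
  write_traces(trs, file.path(d, "traces.csv"))
  got <- read.csv(file.path(d, "traces.csv"))
  expect_equal(nrow(got), n_frames(rv$frames) - 1)
  expect_true(file.exists(file.path(d, "traces_flash.csv")))
  fl <- read.csv(file.path(d, "traces_flash.csv"))
  expect_lte(abs(fl$flash_frame - 31), 1)
})
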