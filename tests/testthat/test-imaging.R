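test_that("ROI intensity extraction averages masks and tracks the top-quench subset", {
  stack <- uniform_stack(value = 100)
  masks <- list(h2o2 = matrix(FALSE, 20, 30), reference = matrix(FALSE, 20, 30))
  masks$h2o2[1:15, 1:20] <- TRUE      # 300 pixels
  masks$reference[18:20, 25:30] <- TRUE
  rois <- roi_set(masks, c(0, 0))
  expect_equal(roi_intensity_series(stack, rois, "h2o2", "mean"),
               rep(100, 30))
  expect_equal(suppressWarnings(
    roi_intensity_series(stack, rois, "h2o2", "top-quench")), rep(100, 30))

  # 200 of 300 pixels decay to 50, the rest stay at 100
  sel <- which(masks$h2o2)
  decayers <- sel[1:200]
  frames <- stack$frames
  for (i in 11:30) {
    fr <- frames[, , i]
    fr[decayers] <- 100 - 50 * (i - 10) / 20
    frames[, , i] <- fr
  }
  stack2 <- frame_stack(stack$times, frames, 0.01, 10)
  top <- roi_intensity_series(stack2, rois, "h2o2", "top-quench")
  expect_equal(top[30], 50)
  expect_equal(top[1], 100)
  # mean mode mixes both populations
  expect_equal(roi_intensity_series(stack2, rois, "h2o2", "mean")[30],
               (200 * 50 + 100 * 100) / 300)
})

test_that("top-quench selection equals exhaustive first-minus-last ranking", {
  set.seed(9)
  dims <- c(15L, 25L)
  n_frames <- 12L
  frames <- array(rnorm(prod(dims) * n_frames, 1000, 5), c(dims, n_frames))
  mask <- matrix(TRUE, dims[1], dims[2])
  rois <- roi_set(list(h2o2 = mask), c(0, 0))
  stack <- frame_stack(seq_len(n_frames), frames, 0.01, t_stress = 3)
  got <- roi_intensity_series(stack, rois, "h2o2", "top-quench", n_top = 50L)
  # oracle: rank pixels by first-to-last drop, average the top 50 per frame
  flat <- matrix(frames, prod(dims), n_frames)
  keep <- order(flat[, 1] - flat[, n_frames], decreasing = TRUE)[1:50]
  expect_equal(got, colMeans(flat[keep, ]))
})

test_that("ratiometric normalization cancels shared multiplicative drift exactly", {
  times <- seq(0, 60, by = 1)
  drift <- 1 + 0.2 * sin(2 * pi * times / 25) + 0.01 * times
  active <- 800 * drift
  reference <- 1200 * drift
  r <- ratiometric_series(active, reference, times, t_stress = 10)
  expect_equal(r, rep(0, length(times)), tolerance = 1e-12)
  # active halves after stress, reference flat: quench = 0.5 post-stress
  act2 <- ifelse(times >= 10, 400, 800)
  r2 <- ratiometric_series(act2, rep(1200, length(times)), times,
                           t_stress = 10, window = 1L)
  expect_equal(r2[times >= 10], rep(0.5, sum(times >= 10)))
  expect_equal(r2[times < 10], rep(0, sum(times < 10)))
  expect_error(ratiometric_series(active, c(0, reference[-1]), times, 10),
               class = "phytowave_data_quality_error")
})

test_that("moving average preserves constants and averages locally", {
  expect_equal(moving_average(rep(7, 40), 10), rep(7, 40))
  x <- sin(seq(0, 4 * pi, length.out = 100))
  sm <- moving_average(x, 10)
  expect_lt(stats::sd(sm), stats::sd(x))
  expect_equal(moving_average(x, 1), x)
})

test_that("quench series convert through the calibration curve with clip accounting", {
  cv <- calibration_curve("SA", kd = 32, r_max = 0.462)
  times <- seq(0, 30, 1)
  z <- series_to_concentration(rep(0, 31), times, cv, t_stress = 10)
  expect_true(all(z$values == 0))
  half <- series_to_concentration(rep(0.231, 31), times, cv, t_stress = 10)
  expect_equal(half$values, rep(32, 31))
  mixed <- series_to_concentration(c(rep(-0.01, 5), rep(0.1, 20), rep(0.99, 6)),
                                   times, cv, t_stress = 10)
  expect_identical(attr(mixed, "n_clipped_negative"), 5L)
  expect_identical(attr(mixed, "n_saturated"), 6L)
  expect_equal(max(mixed$values), 320)   # 10 * kd ceiling
})

test_that("pixel-wise maps match the calibration identities and the series pathway", {
  dims <- c(24L, 24L)
  n_frames <- 40L
  times <- seq(0, by = 1, length.out = n_frames)
  cv <- calibration_curve("SA", kd = 32, r_max = 0.462)
  masks <- list(sa = matrix(FALSE, dims[1], dims[2]),
                reference = matrix(FALSE, dims[1], dims[2]))
  masks$sa[4:12, 4:12] <- TRUE
  masks$reference[16:22, 16:22] <- TRUE
  rois <- roi_set(masks, c(0, 0))

  # no post-stress change: zero map everywhere inside the ROI
  frames <- array(5000, c(dims, n_frames))
  stack <- frame_stack(times, frames, 0.01, t_stress = 10)
  cm <- concentration_map(stack, rois, list(sa = cv), window = 1L)
  expect_true(all(cm$maps[, , n_frames][masks$sa] == 0))
  expect_true(all(is.na(cm$maps[, , n_frames][!masks$sa])))

  # one pixel quenched to half-saturation reads kd, neighbours stay 0
  px <- which(masks$sa)[10]
  for (i in 21:40) {
    fr <- frames[, , i]; fr[px] <- 5000 * (1 - 0.231); frames[, , i] <- fr
  }
  stack2 <- frame_stack(times, frames, 0.01, t_stress = 10)
  cm2 <- concentration_map(stack2, rois, list(sa = cv), window = 1L)
  expect_equal(cm2$maps[, , 40][px], 32, tolerance = 1e-9)
  expect_equal(sum(cm2$maps[, , 40][masks$sa]), 32, tolerance = 1e-9)

  # map averaged over the ROI agrees with the scalar series pathway
  cfg <- small_config(noise_sd = 0, drift_amplitude = 0)
  truth <- make_fields(cfg)
  rendered <- render_stack(truth, cfg)
  cm3 <- concentration_map(rendered$stack, rendered$rois, default_curves(),
                           labels = "sa")
  roi_mean <- vapply(seq_along(cm3$times), function(i)
    mean(cm3$maps[, , i][rendered$rois$masks$sa]), numeric(1))
  s <- stack_to_series(rendered$stack, rendered$rois, default_curves(), "sa")
  expect_lt(max(abs(roi_mean - s$values)), 0.05 * max(s$values) + 0.01)
})

test_that("frame stacks and ROI sets survive a TIFF round trip", {
  skip_if_not_installed("tiff")
  cfg <- small_config(duration = 20)
  rendered <- render_stack(make_fields(cfg), cfg)
  dir <- tempfile(); dir.create(dir)
  path <- file.path(dir, "stack.tif")
  write_frame_stack(rendered$stack, path)
  back <- read_frame_stack(path)
  expect_equal(back$times, rendered$stack$times)
  expect_equal(back$t_stress, rendered$stack$t_stress)
  expect_equal(back$frames, rendered$stack$frames, tolerance = 1e-6)
  write_roi_set(rendered$rois, file.path(dir, "roi"))
  rois2 <- read_roi_set(file.path(dir, "roi"))
  expect_identical(rois2$masks$sa, rendered$rois$masks$sa)
  expect_equal(rois2$stress_site, rendered$rois$stress_site)
})
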