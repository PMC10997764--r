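triangle_series <- function(w = 20, h = 8, t_peak = 60, t_stress = 10,
                            dt = 1, baseline = 0) {
  times <- seq(0, 150, by = dt)
  v <- baseline + h * pmax(0, 1 - abs(times - t_peak) / w)
  concentration_series(times, v, t_stress = t_stress)
}

test_that("FWHM of canonical pulse shapes matches closed forms", {
  # symmetric triangle of base half-width w: FWHM = w
  expect_equal(wave_fwhm(triangle_series(w = 20)), 20, tolerance = 1e-9)
  expect_equal(wave_fwhm(triangle_series(w = 7.5)), 7.5, tolerance = 1e-9)
  # Gaussian pulse: FWHM = 2*sqrt(2*log(2))*sigma, within one grid step
  times <- seq(0, 200, by = 1)
  for (sigma in c(6, 11, 17)) {
    v <- 5 * exp(-(times - 80)^2 / (2 * sigma^2))
    s <- concentration_series(times, v, t_stress = 10)
    expect_equal(wave_fwhm(s), 2.3548 * sigma, tolerance = 1 / (2.3548 * sigma))
  }
})

test_that("FWHM equals a brute-force midpoint-crossing scan on asymmetric pulses", {
  times <- seq(0, 150, by = 1)
  set.seed(5)
  for (i in 1:10) {
    rise <- runif(1, 3, 15); fall <- runif(1, 10, 50); h <- runif(1, 2, 20)
    v <- h * ifelse(times < 50, exp(-(times - 50)^2 / (2 * rise^2)),
                    exp(-(times - 50) / fall))
    s <- concentration_series(times, v, t_stress = 10)
    expect_equal(wave_fwhm(s), fwhm_bruteforce(times, v, 10),
                 tolerance = 1e-3)
  }
})

test_that("FWHM is invariant to vertical scaling and baseline shifts", {
  s <- triangle_series(w = 16, h = 4)
  ref <- wave_fwhm(s)
  for (scale in c(0.2, 3, 40)) {
    s2 <- concentration_series(s$times, s$values * scale, t_stress = 10)
    expect_equal(wave_fwhm(s2), ref, tolerance = 1e-9)
  }
  s3 <- concentration_series(s$times, s$values + 12, t_stress = 10)
  expect_equal(wave_fwhm(s3), ref, tolerance = 1e-9)
})

test_that("one-sided waves raise a flank-naming error", {
  times <- seq(0, 100, by = 1)
  rising <- concentration_series(times, pmax(0, times - 40), t_stress = 10)
  expect_error(wave_fwhm(rising), "falling")
})

test_that("onset detection finds sustained deviations and ignores null traces", {
  times <- seq(0, 200, by = 1)
  flat <- concentration_series(times, rep(2, length(times)), t_stress = 10)
  expect_true(is.na(onset_time(flat)))
  # a step of 10 baseline SDs at t_stress + 30
  set.seed(2)
  base_noise <- rnorm(length(times), 0, 0.3)
  v <- 2 + base_noise + ifelse(times >= 40, 10 * 0.3, 0)
  step <- concentration_series(times, v, t_stress = 10)
  expect_equal(onset_time(step, k_sd = 3, sd_floor = 0), 30, tolerance = 1)
  # onset is non-decreasing in the SD multiplier
  ramp <- concentration_series(times, 2 + pmax(0, (times - 40) / 50),
                               t_stress = 10)
  ons <- vapply(c(0.5, 1, 2, 4, 8), function(k)
    onset_time(ramp, k_sd = k, sd_floor = 0.05), numeric(1))
  expect_true(all(diff(ons) >= 0))
  expect_error(onset_time(concentration_series(9:40, rep(0, 32), t_stress = 10)),
               "baseline")
})

test_that("production and decay rates convert band slopes to uM per hour", {
  times <- seq(0, 100, by = 1)
  # rise at exactly 1 uM/min to a peak then symmetric fall
  v <- pmax(0, 30 - abs(times - 50))
  s <- concentration_series(times, v, t_stress = 5)
  r <- production_decay_rates(s)
  expect_equal(unname(r["production"]), 60, tolerance = 1e-9)
  expect_equal(unname(r["decay"]), 60, tolerance = 1e-9)
  # asymmetric triangle: production and decay differ accordingly
  v2 <- pmax(0, pmin((times - 20) * 2, 40 - (times - 40) * 0.5))
  s2 <- concentration_series(times, pmax(v2, 0), t_stress = 5)
  r2 <- production_decay_rates(s2)
  expect_equal(unname(r2["production"]), 120, tolerance = 0.05)
  expect_equal(unname(r2["decay"]), 30, tolerance = 0.05)
  # too-coarse sampling inside the band is an explicit error
  coarse <- concentration_series(c(0, 6, 12, 18, 24), c(0, 0, 10, 0, 0),
                                 t_stress = 3)
  expect_error(production_decay_rates(coarse), class = "phytowave_band_error")
})

test_that("the rate curve is the scaled derivative at 15-minute marks", {
  times <- seq(0, 120, by = 1)
  const <- concentration_series(times, rep(4, length(times)), t_stress = 10)
  expect_true(all(rate_curve(const)$rate_uM_per_h == 0))
  lin <- concentration_series(times, 0.3 * times, t_stress = 10)
  rc <- rate_curve(lin)
  expect_equal(rc$rate_uM_per_h, rep(18, nrow(rc)), tolerance = 1e-9)
  quad <- concentration_series(times, times^2, t_stress = 10)
  rcq <- rate_curve(quad)
  expect_equal(rcq$rate_uM_per_h[rcq$time_min == 30], 3600, tolerance = 1e-9)
})

test_that("SA wave velocity reproduces the printed distance/onset ratios", {
  expect_identical(sa_wave_velocity(1.0, 87.0), 0.011)
  expect_identical(sa_wave_velocity(1.0, 22.5), 0.044)
  expect_identical(sa_wave_velocity(1.0, 35.5), 0.028)
  # linear in distance, inverse in time
  expect_equal(sa_wave_velocity(2.0, 87.0), round(2 * 1 / 87, 3))
  expect_equal(sa_wave_velocity(1.0, 43.5), round(1 / 43.5, 3))
  expect_error(sa_wave_velocity(1.0, NA_real_),
               class = "phytowave_undefined_velocity")
  expect_error(sa_wave_velocity(0, 10), class = "phytowave_input_error")
})

test_that("front tracking recovers a constructed constant-speed plane wave", {
  dims <- c(60L, 20L)
  times <- seq(0, 30, by = 0.5)
  speed <- 0.20; px <- 0.01
  maps <- array(0, c(dims, length(times)))
  m0 <- matrix(0, dims[1], dims[2])
  dist <- sqrt((row(m0) - 1)^2 + (col(m0) - 11)^2) * px
  for (i in seq_along(times)) {
    maps[, , i][dist <= speed * times[i]] <- 10
  }
  cmap <- concentration_map_obj(times, maps, px)
  v <- ros_front_velocity(cmap, stress_site = c(0, 10))
  expect_equal(v, speed, tolerance = 0.05)
  # a stationary field has no propagating front
  flat <- concentration_map_obj(times, array(10, c(dims, length(times))), px)
  expect_error(ros_front_velocity(flat, c(0, 10)),
               class = "phytowave_insufficient_front")
})
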