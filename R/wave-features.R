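#' Concentration time series for one sensor spot
#'
#' @param times minutes, strictly increasing, near-uniform.
#' @param values mean concentration, uM.
#' @param stderr optional per-time standard error, uM.
#' @param t_stress stress time, min; must lie within the time range.
#' @param replicate_count integer >= 1.
#' @return object of class \code{concentration_series}.
#' @export
concentration_series <- function(times, values, stderr = NULL,
                                 t_stress, replicate_count = 1L) {
  if (length(times) != length(values))
    stop_input("times and values must have the same length")
  assert_increasing(times)
  if (t_stress < min(times) || t_stress > max(times))
    stop_input("t_stress must lie within the time range")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 stderr = stderr, t_stress = t_stress,
                 replicate_count = as.integer(replicate_count)),
            class = "concentration_series")
}

#' @keywords internal
#' @noRd
series_baseline <- function(series) {
  pre <- series$times < series$t_stress
  if (!any(pre)) 0 else mean(series$values[pre])
}

#' @keywords internal
#' @noRd
series_peak <- function(series) {
  post <- which(series$times >= series$t_stress)
  if (!length(post)) stop_input("no samples at or after t_stress")
  i <- post[which.max(series$values[post])]
  list(index = i, time = series$times[i], value = series$values[i])
}

#' Interpolated level crossing nearest the peak on one flank
#' @keywords internal
#' @noRd
flank_crossing <- function(times, values, level, peak_index, side) {
  if (side == "left") {
    idx <- seq_len(peak_index - 1L)
    below <- idx[values[idx] < level]
    if (!length(below)) return(NA_real_)
    i <- max(below)                       # crossing nearest the peak
  } else {
    idx <- seq(peak_index + 1L, length(values))
    if (peak_index >= length(values)) return(NA_real_)
    below <- idx[values[idx] < level]
    if (!length(below)) return(NA_real_)
    i <- min(below)
  }
  j <- if (side == "left") i + 1L else i - 1L
  # linear interpolation between the bracketing samples
  t0 <- times[i]; t1 <- times[j]; v0 <- values[i]; v1 <- values[j]
  if (v1 == v0) return(t1)
  t0 + (level - v0) * (t1 - t0) / (v1 - v0)
}

#' Full width at half maximum of a concentration wave
#'
#' Locates the global post-stress peak, takes the pre-stress mean as the
#' baseline, and returns the time between the two crossings of
#' baseline + amplitude/2, one on each flank, with linear interpolation
#' between samples. When a flank crosses the half level several times, the
#' crossing nearest the peak is used.
#'
#' @param series a \code{\link{concentration_series}} with an interior
#'   post-stress maximum above baseline.
#' @return FWHM in minutes.
#' @export
wave_fwhm <- function(series) {
  stopifnot(inherits(series, "concentration_series"))
  base <- series_baseline(series)
  pk <- series_peak(series)
  amp <- pk$value - base
  if (amp <= 0) stop_input("no peak above baseline")
  half <- base + amp / 2
  t_left <- flank_crossing(series$times, series$values, half, pk$index, "left")
  t_right <- flank_crossing(series$times, series$values, half, pk$index, "right")
  if (is.na(t_left))
    stop(structure(class = c("phytowave_onesided_wave_error", "error", "condition"),
                   list(message = "no half-maximum crossing on the left (rising) flank",
                        call = sys.call())))
  if (is.na(t_right))
    stop(structure(class = c("phytowave_onesided_wave_error", "error", "condition"),
                   list(message = "no half-maximum crossing on the right (falling) flank",
                        call = sys.call())))
  t_right - t_left
}

#' Onset time of sustained signal elevation
#'
#' The first post-stress time at which the value exceeds
#' baseline mean + k_sd * baseline SD for \code{sustain} consecutive
#' samples, reported relative to \code{t_stress}; \code{NA} when the
#' signal never deviates (e.g. the wounding SA trace). When the baseline
#' SD is exactly zero (noise-free synthetic truth), an absolute floor is
#' used instead so the criterion stays meaningful.
#'
#' @param series a \code{\link{concentration_series}}.
#' @param baseline_window minutes of pre-stress data used for the baseline;
#'   default all frames before t_stress. Must contain >= 3 points.
#' @param k_sd SD multiplier, default 3. Smoothed series carry strongly
#'   autocorrelated noise, so a 1-SD criterion fires spuriously; the
#'   classic 3-sigma rule with sustained exceedance is robust to it.
#' @param sustain consecutive points required above threshold, default 3.
#' @param sd_floor absolute SD floor in uM, default 0.05. The floor is a
#'   minimum on the baseline SD: short smoothed baselines contain only a
#'   couple of independent noise values and can underestimate their own
#'   SD severely, and noise-free synthetic truth has SD exactly zero.
#' @return onset in minutes after t_stress, or \code{NA_real_}.
#' @export
onset_time <- function(series, baseline_window = NULL, k_sd = 3,
                       sustain = 3L, sd_floor = 0.05) {
  stopifnot(inherits(series, "concentration_series"))
  pre <- series$times < series$t_stress
  if (!is.null(baseline_window))
    pre <- pre & series$times >= (series$t_stress - baseline_window)
  if (sum(pre) < 3L) stop_input("baseline window must contain >= 3 points")
  mu <- mean(series$values[pre])
  sd0 <- stats::sd(series$values[pre])
  if (!is.finite(sd0)) sd0 <- sd_floor
  sd0 <- max(sd0, sd_floor)
  thr <- mu + k_sd * sd0
  post <- which(series$times >= series$t_stress)
  above <- series$values[post] > thr
  if (!any(above)) return(NA_real_)
  run <- rle(above)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1L
  ok <- which(run$values & run$lengths >= sustain)
  if (!length(ok)) return(NA_real_)
  series$times[post[starts[ok[1L]]]] - series$t_stress
}

#' @keywords internal
#' @noRd
band_slope <- function(times, values, lo_level, hi_level, idx) {
  sel <- idx[values[idx] >= lo_level & values[idx] <= hi_level]
  if (length(sel) < 2L)
    stop(structure(class = c("phytowave_band_error", "error", "condition"),
                   list(message = paste0(
                     "fewer than 2 samples between the 10% and 90% amplitude ",
                     "levels; sample the wave more finely"), call = sys.call())))
  unname(stats::coef(stats::lm(values[sel] ~ times[sel]))[2L])
}

#' Initial production and decay rates of a wave
#'
#' Production is the least-squares slope through the samples between 10%
#' and 90% of the peak amplitude on the rising flank; decay is the absolute
#' slope over the 90% to 10% band on the falling flank, truncated to the
#' end of the record when the wave never falls back to 10% (slow-decay,
#' heat-like waves). Both are returned in uM/h.
#'
#' @param series a \code{\link{concentration_series}} with a peak.
#' @param band amplitude band fractions, default c(0.10, 0.90).
#' @return named numeric vector c(production = ..., decay = ...) in uM/h.
#' @export
production_decay_rates <- function(series, band = c(0.10, 0.90)) {
  stopifnot(inherits(series, "concentration_series"))
  base <- series_baseline(series)
  pk <- series_peak(series)
  amp <- pk$value - base
  if (amp <= 0) stop_input("no peak above baseline")
  lo <- base + band[1L] * amp
  hi <- base + band[2L] * amp
  n <- length(series$times)
  # rising flank: contiguous run ending at the peak, from the last sample
  # below the 10% level before the peak
  rise_start <- 1L
  below <- which(series$values[seq_len(pk$index)] < lo)
  if (length(below)) rise_start <- max(below)
  rise_idx <- seq(rise_start, pk$index)
  prod_rate <- band_slope(series$times, series$values, lo, hi, rise_idx)
  # falling flank: from the peak to where the primary wave stops falling —
  # the first sample below the 10% level, or the point where the series
  # turns back up by more than 5% of the amplitude above its running
  # minimum (the inter-burst dip preceding a secondary burst); record end
  # for slow monotone decay
  fall_end <- pk$index
  run_min <- pk$value
  for (i in seq(pk$index, n)) {
    v <- series$values[i]
    if (v < lo || v > run_min + 0.05 * amp) break
    run_min <- min(run_min, v)
    fall_end <- i
  }
  fall_idx <- seq(pk$index, fall_end)
  decay_rate <- abs(band_slope(series$times, series$values, lo, hi, fall_idx))
  c(production = 60 * prod_rate, decay = 60 * decay_rate)
}

#' Rate curve: derivative of a concentration series at fixed steps
#'
#' Central-difference derivative of the series evaluated at every multiple
#' of \code{step} minutes within the record, converted to uM/h.
#'
#' @param series a \code{\link{concentration_series}} spanning >= 2 steps.
#' @param step evaluation spacing in minutes, default 15.
#' @return data.frame with columns \code{time_min} and \code{rate_uM_per_h}.
#' @export
rate_curve <- function(series, step = 15) {
  stopifnot(inherits(series, "concentration_series"))
  t0 <- series$times[1L]; t1 <- series$times[length(series$times)]
  if (t1 - t0 < 2 * step) stop_input("series must span at least 2 steps")
  eval_t <- seq(ceiling(t0 / step) * step, floor(t1 / step) * step, by = step)
  dt <- stats::median(diff(series$times))
  f <- stats::approxfun(series$times, series$values, rule = 2)
  rate <- (f(pmin(eval_t + dt, t1)) - f(pmax(eval_t - dt, t0))) /
    (pmin(eval_t + dt, t1) - pmax(eval_t - dt, t0))
  data.frame(time_min = eval_t, rate_uM_per_h = 60 * rate)
}

#' SA wave velocity from onset time and source distance
#'
#' The SA front velocity is estimated as the ratio of the distance between
#' the stress-application site and the sensor spot to the mean SA onset
#' time, reported in cm/min rounded to 3 decimals (the field's printed
#' precision).
#'
#' @param distance_cm distance from the stress site to the sensor spot, cm.
#' @param onset_min mean SA onset time, min; \code{NA} (no onset detected)
#'   raises an undefined-velocity error.
#' @return velocity in cm/min (3 decimals).
#' @export
sa_wave_velocity <- function(distance_cm, onset_min) {
  if (is.na(onset_min))
    stop(structure(class = c("phytowave_undefined_velocity", "error", "condition"),
                   list(message = "no SA onset detected: wave velocity undefined",
                        call = sys.call())))
  if (distance_cm <= 0 || onset_min <= 0)
    stop_input("distance and onset must be > 0")
  round(distance_cm / onset_min, 3)
}

#' ROS front velocity from a concentration map
#'
#' Bins pixels by Euclidean distance from the stress site; a bin's arrival
#' time is the first frame whose bin-median concentration exceeds the
#' threshold; the velocity is the least-squares slope of distance versus
#' arrival time.
#'
#' @param cmap a \code{\link{concentration_map}}.
#' @param stress_site pixel coordinate c(row, col), 0-based.
#' @param threshold_uM arrival threshold; default 25% of the spatial peak
#'   concentration over the whole record.
#' @param bin_width_cm distance bin width, default 0.05 cm.
#' @param mask optional logical matrix restricting the analysis (e.g. one
#'   sensor ROI).
#' @return velocity in cm/min (3 decimals).
#' @export
ros_front_velocity <- function(cmap, stress_site, threshold_uM = NULL,
                               bin_width_cm = 0.05, mask = NULL) {
  stopifnot(inherits(cmap, "concentration_map"))
  dims <- dim(cmap$maps)[1:2]
  if (is.null(mask)) mask <- matrix(TRUE, dims[1L], dims[2L])
  rows <- row(mask) - 1L; cols <- col(mask) - 1L
  dist_cm <- sqrt((rows - stress_site[1L])^2 + (cols - stress_site[2L])^2) *
    cmap$pixel_size
  sel <- which(mask)
  vals <- matrix(cmap$maps, prod(dims), dim(cmap$maps)[3L])[sel, , drop = FALSE]
  if (is.null(threshold_uM)) threshold_uM <- 0.25 * max(vals)
  bins <- floor(dist_cm[sel] / bin_width_cm)
  bin_ids <- sort(unique(bins))
  arrivals <- vapply(bin_ids, function(b) {
    med <- apply(vals[bins == b, , drop = FALSE], 2L, stats::median)
    hit <- which(med > threshold_uM)
    if (!length(hit)) NA_real_ else cmap$times[hit[1L]]
  }, numeric(1))
  d_mid <- (bin_ids + 0.5) * bin_width_cm
  ok <- !is.na(arrivals)
  if (sum(ok) < 3L || length(unique(arrivals[ok])) < 2L)
    stop(structure(class = c("phytowave_insufficient_front", "error", "condition"),
                   list(message = "fewer than 3 distance bins with distinct threshold crossings",
                        call = sys.call())))
  round(unname(stats::coef(stats::lm(d_mid[ok] ~ arrivals[ok]))[2L]), 3)
}

#' Extract the full wave-feature set from a concentration series
#'
#' @param series a \code{\link{concentration_series}}.
#' @param distance_cm optional distance from stress site to sensor spot
#'   for the SA velocity.
#' @param ... passed to \code{\link{onset_time}}.
#' @return object of class \code{wave_features}: list with peak_time,
#'   peak_value, fwhm, production_rate, decay_rate, onset_time, velocity.
#'   Peak-dependent fields are \code{NA} when there is no peak above
#'   baseline.
#' @export
wave_features <- function(series, distance_cm = NULL, ...) {
  stopifnot(inherits(series, "concentration_series"))
  onset <- onset_time(series, ...)
  feat <- list(peak_time = NA_real_, peak_value = NA_real_, fwhm = NA_real_,
               production_rate = NA_real_, decay_rate = NA_real_,
               onset_time = onset, velocity = NA_real_)
  if (!is.na(onset)) {
    pk <- series_peak(series)
    base <- series_baseline(series)
    if (pk$value > base) {
      feat$peak_time <- pk$time
      feat$peak_value <- pk$value
      feat$fwhm <- tryCatch(wave_fwhm(series), error = function(e) NA_real_)
      rates <- tryCatch(production_decay_rates(series),
                        error = function(e) c(production = NA_real_, decay = NA_real_))
      feat$production_rate <- unname(rates["production"])
      feat$decay_rate <- unname(rates["decay"])
    }
    if (!is.null(distance_cm))
      feat$velocity <- sa_wave_velocity(distance_cm, onset)
  }
  structure(feat, class = "wave_features")
}

#' Write wave features as one CSV row per experiment
#'
#' @param features named list of \code{\link{wave_features}} objects, one
#'   per stress label.
#' @param path file path.
#' @export
write_features_csv <- function(features, path) {
  rows <- lapply(names(features), function(lbl) {
    f <- features[[lbl]]
    data.frame(stress_label = lbl, peak_time_min = f$peak_time,
               peak_uM = f$peak_value, fwhm_min = f$fwhm,
               production_uM_per_h = f$production_rate,
               decay_uM_per_h = f$decay_rate, onset_min = f$onset_time,
               velocity_cm_per_min = f$velocity)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
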