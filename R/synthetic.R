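#' Configuration for the synthetic stress-experiment generator
#'
#' Describes one simulated multiplexed-nanosensor experiment: a leaf patch
#' on a pixel grid carrying two to three sensor spots (SA, H2O2, reference),
#' a stress applied at \code{t_stress} at \code{stress_site}, a traveling
#' H2O2 wave whose local waveform is the reaction network's A(t), a delayed
#' diffusive SA plume following the network's S(t), shared multiplicative
#' drift and additive detector noise.
#'
#' @param stress_label one of "wounding", "xcc", "light", "heat", "null".
#' @param grid c(rows, cols), default c(128, 128).
#' @param pixel_size cm per pixel, default 0.01.
#' @param frame_interval minutes per frame, default 0.5 (30-s exposures).
#' @param duration total record length, minutes, default 240.
#' @param t_stress stress time, minutes, default 10.
#' @param kinetic_params a \code{\link{kinetic_params}} (local waveform
#'   truth), or NULL for the "null" treatment.
#' @param wave_speed H2O2 front speed, cm/min.
#' @param sa_onset source SA appearance time, minutes post-stress; NULL for
#'   wounding/null (no SA).
#' @param sa_diffusion SA plume diffusion coefficient, cm^2/min.
#' @param sa_sigma0 initial SA source spot SD, cm (default 0.25).
#' @param sa_amp dimensionless scale applied to the kinetic S(t) waveform
#'   at the source center (default 1).
#' @param stress_site pixel c(row, col), 0-based.
#' @param roi_layout a \code{\link{roi_set}}; default spot layout from
#'   \code{\link{make_roi_layout}}.
#' @param drift_amplitude shared multiplicative drift amplitude (fraction),
#'   default 0.05.
#' @param noise_sd additive noise SD as a fraction of baseline intensity,
#'   default 0.01.
#' @param seed RNG seed for rendering, default 0.
#' @return object of class \code{synth_config}.
#' @export
synth_config <- function(stress_label, grid = c(128L, 128L), pixel_size = 0.01,
                         frame_interval = 0.5, duration = 240, t_stress = 10,
                         kinetic_params = NULL, wave_speed = 0.2,
                         sa_onset = NULL, sa_diffusion = 0.01,
                         sa_sigma0 = 0.25, sa_amp = 1,
                         stress_site = c(8, round(grid[2L] / 2)),
                         roi_layout = NULL, drift_amplitude = 0.05,
                         noise_sd = 0.01, seed = 0L) {
  stress_label <- match.arg(stress_label,
                            c("wounding", "xcc", "light", "heat", "null"))
  if (duration <= t_stress) stop_input("duration must exceed t_stress")
  if (!is.null(sa_onset) && sa_onset < 0)
    stop_input("sa_onset must be >= 0 (minutes post-stress)")
  if (is.null(roi_layout))
    roi_layout <- make_roi_layout(grid, stress_site)
  structure(list(stress_label = stress_label, grid = as.integer(grid),
                 pixel_size = pixel_size, frame_interval = frame_interval,
                 duration = duration, t_stress = t_stress,
                 kinetic_params = kinetic_params, wave_speed = wave_speed,
                 sa_onset = sa_onset, sa_diffusion = sa_diffusion,
                 sa_sigma0 = sa_sigma0, sa_amp = sa_amp,
                 stress_site = as.numeric(stress_site),
                 roi_layout = roi_layout,
                 drift_amplitude = drift_amplitude, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Default sensor-spot layout on the synthetic leaf
#'
#' style "spots": three disjoint circular spots (radius 9 px, about 250
#' pixels each) with the SA spot centered exactly 1.0 cm down-leaf from the
#' stress site, mimicking infiltration on either side of the midvein. The
#' H2O2 spot sits nearer the stress site (0.29 cm) so that even the slowest
#' fronts reach it within a few minutes; its distance is not a calibrated
#' quantity, only the SA spot's 1.0 cm enters the velocity ratio.
#' style "strip": an elongated H2O2 sensor band along the propagation axis
#' (for front-velocity tracking) plus SA and reference spots beside it.
#'
#' @param grid c(rows, cols).
#' @param stress_site pixel c(row, col), 0-based.
#' @param style "spots" or "strip".
#' @param radius_px spot radius in pixels, default 9.
#' @return a \code{\link{roi_set}}.
#' @export
make_roi_layout <- function(grid, stress_site, style = c("spots", "strip"),
                            radius_px = 9L) {
  style <- match.arg(style)
  disk <- function(center, r) {
    m <- matrix(FALSE, grid[1L], grid[2L])
    rows <- row(m) - 1L; cols <- col(m) - 1L
    (rows - center[1L])^2 + (cols - center[2L])^2 <= r^2
  }
  r0 <- stress_site[1L]; c0 <- stress_site[2L]
  if (style == "spots") {
    masks <- list(
      sa = disk(c(r0 + 100, c0), radius_px),
      h2o2 = disk(c(r0 + 25, c0 - 15), radius_px),
      reference = disk(c(r0 + 100, c0 + 28), radius_px))
  } else {
    m <- matrix(FALSE, grid[1L], grid[2L])
    rows <- row(m) - 1L; cols <- col(m) - 1L
    band <- rows >= r0 + 10 & rows <= r0 + 110 &
      abs(cols - (c0 - 20)) <= 6
    masks <- list(
      sa = disk(c(r0 + 100, c0 + 14), radius_px),
      h2o2 = band,
      reference = disk(c(r0 + 100, c0 + 40), radius_px))
  }
  roi_set(masks, stress_site)
}

#' @keywords internal
#' @noRd
pixel_distances_cm <- function(grid, stress_site, pixel_size) {
  m <- matrix(0, grid[1L], grid[2L])
  rows <- row(m) - 1L; cols <- col(m) - 1L
  sqrt((rows - stress_site[1L])^2 + (cols - stress_site[2L])^2) * pixel_size
}

#' Ground-truth concentration fields and features for a synthetic run
#'
#' H2O2 at each pixel is the reaction network's A(t) waveform time-shifted
#' by distance/wave_speed (a constant-speed traveling wave). SA is zero
#' everywhere until \code{sa_onset}, then a two-dimensional Gaussian plume
#' centered at the stress site whose variance grows as
#' sigma0^2 + 2 * sa_diffusion * (t - onset) and whose total amount follows
#' the network's S(t) waveform (mass-conserving spreading: the center
#' dilutes as the plume widens). Wounding and null presets produce no SA.
#'
#' @param config a \code{\link{synth_config}}.
#' @return object of class \code{ground_truth}: list with \code{times},
#'   \code{h2o2_field} and \code{sa_field} (rows x cols x frames arrays,
#'   uM), \code{features} (per-ROI \code{\link{wave_features}} from the
#'   noise-free fields), \code{velocities}, \code{sa_distance_cm}.
#' @export
make_fields <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  times <- seq(0, config$duration, by = config$frame_interval)
  grid <- config$grid
  nt <- length(times)
  h2o2 <- array(0, c(grid, nt))
  sa <- array(0, c(grid, nt))
  dist <- pixel_distances_cm(grid, config$stress_site, config$pixel_size)

  traj <- NULL
  if (config$stress_label != "null" && !is.null(config$kinetic_params)) {
    kp <- config$kinetic_params
    t_fine <- seq(0, config$duration + max(dist) / config$wave_speed,
                  by = min(0.25, config$frame_interval / 2))
    t_fine <- sort(unique(c(t_fine, kp$t_stress)))
    traj <- simulate_network(kp, t_fine)
    fA <- stats::approxfun(traj$times, traj$species[, "A"], rule = 2)
    fS <- stats::approxfun(traj$times, traj$species[, "S"], rule = 2)
    delay <- dist / config$wave_speed
    for (i in seq_len(nt)) {
      tl <- times[i] - delay
      a <- fA(pmax(tl, 0))
      a[tl < kp$t_stress] <- 0
      h2o2[, , i] <- a
    }
    if (!is.null(config$sa_onset)) {
      t_on <- config$t_stress + config$sa_onset
      s0sq <- config$sa_sigma0^2
      for (i in seq_len(nt)) {
        if (times[i] <= t_on) next
        ssq <- s0sq + 2 * config$sa_diffusion * (times[i] - t_on)
        sa[, , i] <- config$sa_amp * fS(times[i]) * (s0sq / ssq) *
          exp(-dist^2 / (2 * ssq))
      }
    }
  }

  truth <- structure(list(times = times, h2o2_field = h2o2, sa_field = sa,
                          config = config),
                     class = "ground_truth")
  truth$features <- truth_features(truth)
  sa_centroid <- roi_centroid(config$roi_layout$masks$sa)
  truth$sa_distance_cm <- sqrt(sum((sa_centroid - config$stress_site)^2)) *
    config$pixel_size
  sa_onset_meas <- truth$features$sa$onset_time
  truth$velocities <- c(
    h2o2 = if (config$stress_label == "null") NA_real_ else config$wave_speed,
    sa = if (is.null(config$sa_onset) || is.na(sa_onset_meas)) NA_real_
         else sa_wave_velocity(truth$sa_distance_cm, sa_onset_meas))
  truth
}

#' @keywords internal
#' @noRd
roi_centroid <- function(mask) {
  c(mean(row(mask)[mask]) - 1, mean(col(mask)[mask]) - 1)
}

#' @keywords internal
#' @noRd
roi_mean_series <- function(field, mask) {
  npx <- prod(dim(field)[1:2])
  flat <- matrix(field, npx, dim(field)[3L])
  colMeans(flat[which(mask), , drop = FALSE])
}

#' Wave features of the noise-free ground-truth fields at the sensor ROIs
#'
#' The noise-free ROI series are passed through the same 10-point moving
#' average the measurement pipeline applies, so that truth and pipeline
#' features share one measurement operator and round-trip comparisons
#' isolate noise rather than the smoother's bias.
#' @keywords internal
#' @noRd
truth_features <- function(truth, window = 10L) {
  cfg <- truth$config
  masks <- cfg$roi_layout$masks
  mk <- function(field, mask) {
    concentration_series(truth$times,
                         moving_average(roi_mean_series(field, mask), window),
                         t_stress = cfg$t_stress)
  }
  h_series <- mk(truth$h2o2_field, masks$h2o2)
  s_series <- mk(truth$sa_field, masks$sa)
  sa_dist <- sqrt(sum((roi_centroid(masks$sa) - cfg$stress_site)^2)) *
    cfg$pixel_size
  s_feat <- wave_features(s_series)
  if (!is.na(s_feat$onset_time))
    s_feat$velocity <- sa_wave_velocity(sa_dist, s_feat$onset_time)
  list(h2o2 = wave_features(h_series), sa = s_feat)
}

#' Default calibration curves for rendering and processing
#'
#' The SA curve is the fitted in-vitro sensor calibration (K_D 32 uM,
#' r_max 0.462). No published calibration exists for the H2O2 sensor, so a
#' synthetic Langmuir-form placeholder (K_D 100 uM, r_max 0.8) is used and
#' clearly labeled as such; any curve of the same form can be substituted.
#'
#' @return named list of \code{\link{calibration_curve}}s (sa, h2o2).
#' @export
default_curves <- function() {
  list(sa = calibration_curve("SA", kd = 32, r_max = 0.462),
       h2o2 = calibration_curve("H2O2-synthetic", kd = 100, r_max = 0.8))
}

#' Render a ground truth into a noisy nIR frame stack
#'
#' Forward model of the measurement: each sensor pixel emits
#' I_base * (1 - r(c(x, t))) * d(t) + eps, where r is the label's Langmuir
#' response, d(t) a multiplicative drift shared by ALL spots including the
#' reference (slow sinusoid of the configured amplitude plus a 5% linear
#' ramp), and eps Gaussian noise with SD noise_sd * I_base. The reference
#' ROI responds to nothing (r = 0); non-sensor background sits at 2% of
#' I_base. Deterministic under the configured seed.
#'
#' @param truth a \code{\link{make_fields}} result.
#' @param config a \code{\link{synth_config}}.
#' @param curves named list of calibration curves (default
#'   \code{\link{default_curves}}).
#' @param i_base baseline sensor intensity in counts, default 10000.
#' @return list with \code{stack} (a \code{\link{frame_stack}}) and
#'   \code{rois} (a \code{\link{roi_set}}).
#' @export
render_stack <- function(truth, config, curves = default_curves(),
                         i_base = 10000) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "synth_config"))
  times <- truth$times
  nt <- length(times)
  grid <- config$grid
  npx <- prod(grid)
  masks <- config$roi_layout$masks
  drift <- (1 + config$drift_amplitude * sin(2 * pi * times / 60)) *
    (1 + 0.05 * times / config$duration)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(config$seed)

  frames <- array(0.02 * i_base, c(grid, nt))
  field_for <- list(sa = truth$sa_field, h2o2 = truth$h2o2_field,
                    reference = NULL)
  for (lbl in names(masks)) {
    sel <- which(masks[[lbl]])
    fld <- field_for[[lbl]]
    for (i in seq_len(nt)) {
      r <- if (is.null(fld)) 0 else response_at(curves[[lbl]] %||% curves$h2o2,
                                                fld[, , i][sel])
      fr <- frames[, , i]
      fr[sel] <- i_base * (1 - r)
      frames[, , i] <- fr
    }
  }
  for (i in seq_len(nt)) {
    frames[, , i] <- frames[, , i] * drift[i] +
      stats::rnorm(npx, 0, config$noise_sd * i_base)
  }
  frames[frames < 0] <- 0
  list(stack = frame_stack(times, frames, config$pixel_size, config$t_stress),
       rois = config$roi_layout)
}

#' Stress-archetype presets
#'
#' Returns a \code{\link{synth_config}} whose frozen kinetic and transport
#' parameters reproduce, in the noise-free ground truth, the temporal
#' signatures characteristic of each stress: wounding (fast narrow H2O2
#' wave, no SA), Xcc infection (broad wave, late SA onset after the wave
#' has decayed), high light (broad wave, early SA onset, secondary burst),
#' high heat (fast production, very slow decay, intermediate SA onset,
#' secondary burst), and a null (buffer) treatment.
#'
#' @param stress_label preset name.
#' @param ... overrides passed to \code{\link{synth_config}} (e.g.
#'   \code{seed}, \code{grid}, \code{frame_interval}, \code{noise_sd}).
#' @return a \code{\link{synth_config}}.
#' @export
stress_preset <- function(stress_label, ...) {
  stress_label <- match.arg(stress_label,
                            c("wounding", "xcc", "light", "heat", "null"))
  presets <- jsonlite::read_json(
    system.file("extdata", "presets.json", package = "phytowave",
                mustWork = TRUE), simplifyVector = TRUE)
  p <- presets[[stress_label]]
  overrides <- list(...)
  kp <- NULL
  if (!is.null(p$kinetics)) {
    kin <- p$kinetics
    kp <- kinetic_params(k = kin$k, kd = kin$kd, kf1 = kin$kf1,
                         kf_chain = kin$kf_chain, ks = kin$ks,
                         ki = kin$ki, kr = kin$kr,
                         n_intermediates = kin$n_intermediates,
                         a0 = kin$a0, p0 = kin$p0, pf0 = kin$pf0,
                         pi0 = kin$pi0, t_stress = p$t_stress %||% 10,
                         t2 = kin$t2, p2 = kin$p2)
  }
  args <- list(stress_label = stress_label, kinetic_params = kp,
               wave_speed = p$wave_speed %||% 0.2,
               sa_onset = p$sa_onset,
               sa_diffusion = p$sa_diffusion %||% 0.01,
               sa_sigma0 = p$sa_sigma0 %||% 0.25,
               sa_amp = p$sa_amp %||% 1)
  args[names(overrides)] <- overrides
  do.call(synth_config, args)
}
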