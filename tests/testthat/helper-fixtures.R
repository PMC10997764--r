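# Shared in-code fixtures; everything is generated, nothing is stored.

langmuir_titration <- function(kd = 32, r_max = 0.462,
                               conc = c(1, 5, 10, 50, 100, 500),
                               noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  r <- r_max * conc / (kd + conc)
  if (noise_sd > 0) r <- r * (1 + rnorm(length(r), 0, noise_sd))
  titration_data("SA", conc, r)
}

# a compact three-spot layout for small grids
small_roi_layout <- function(grid = c(40L, 40L), stress_site = c(4, 20),
                             radius = 4L) {
  disk <- function(center) {
    m <- matrix(FALSE, grid[1L], grid[2L])
    (row(m) - 1L - center[1L])^2 + (col(m) - 1L - center[2L])^2 <= radius^2
  }
  roi_set(list(sa = disk(c(30, 10)), h2o2 = disk(c(30, 20)),
               reference = disk(c(30, 30))),
          stress_site)
}

# small, fast synthetic configuration (not a tuned stress preset)
small_config <- function(stress_label = "xcc", ...) {
  args <- list(
    stress_label = stress_label,
    grid = c(40L, 40L), stress_site = c(4, 20),
    roi_layout = small_roi_layout(),
    frame_interval = 0.5, duration = 90, t_stress = 10,
    kinetic_params = kinetic_params(k = 0.012, kd = 0.15, kf1 = 1e-4,
                                    kf_chain = c(0.3, 0.3), ks = 0.3,
                                    ki = 2e-4, kr = 0.05, a0 = 0.25, p0 = 40,
                                    pf0 = 150, pi0 = 5, t_stress = 10),
    wave_speed = 0.2, sa_onset = 20, sa_diffusion = 0.01,
    sa_sigma0 = 0.1, sa_amp = 30, noise_sd = 0.01, seed = 1L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synth_config, args)
}

# uniform frame stack builder for imaging unit tests
uniform_stack <- function(value = 100, n_frames = 30L, dims = c(20L, 30L),
                          frame_interval = 1, t_stress = 10) {
  frame_stack(times = seq(0, by = frame_interval, length.out = n_frames),
              frames = array(value, c(dims, n_frames)),
              pixel_size = 0.01, t_stress = t_stress)
}
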