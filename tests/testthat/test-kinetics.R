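test_that("with decay and SA branches off, A follows the closed-form logistic", {
  kp <- kinetic_params(k = 0.05, kd = 0, a0 = 0.5, p0 = 10, t_stress = 10)
  t_grid <- seq(0, 120, by = 1)
  tr <- simulate_network(kp, t_grid)
  N <- kp$a0 + kp$p0
  post <- t_grid >= kp$t_stress
  expected <- N / (1 + ((N - kp$a0) / kp$a0) *
                     exp(-kp$k * N * (t_grid[post] - kp$t_stress)))
  expect_equal(tr$species[post, "A"], expected, tolerance = 1e-6)
  # A + P conserved after the seed appears, saturation at a0 + p0
  expect_equal(unname(tr$species[post, "A"] + tr$species[post, "P"]),
               rep(N, sum(post)), tolerance = 1e-8)
  expect_equal(unname(tr$species[nrow(tr$species), "A"]), N, tolerance = 1e-6)
})

test_that("trajectories match an independent fixed-step RK4 oracle within 0.1%", {
  kp <- kinetic_params(k = 0.01, kd = 0.05, kf1 = 5e-4, kf_chain = 0.1,
                       ks = 0.08, ki = 3e-4, kr = 0.02,
                       n_intermediates = 2L, a0 = 0.3, p0 = 30,
                       pf0 = 60, pi0 = 8, t_stress = 0)
  out_t <- seq(0, 30, by = 0.5)
  tr <- simulate_network(kp, out_t)
  y0 <- stats::setNames(numeric(8), c("A", "P", "B", "pF", "F1", "F2",
                                      "S", "pI"))
  y0 <- c(y0, I = 0, xF1 = 0)
  y0["A"] <- kp$a0; y0["P"] <- kp$p0; y0["pF"] <- kp$pf0; y0["pI"] <- kp$pi0
  oracle <- rk4_integrate(kp, 0, 30, y0, dt = 1e-3, output_times = out_t)
  for (sp in colnames(tr$species)) {
    scale <- max(abs(oracle[, sp]), 1e-8)
    expect_lt(max(abs(tr$species[, sp] - oracle[, sp])) / scale, 1e-3)
  }
})

test_that("stoichiometric conservation laws hold over randomized parameter draws", {
  set.seed(42)
  t_grid <- seq(0, 120, by = 2)
  for (i in 1:100) {
    n <- sample(1:4, 1)
    kp <- kinetic_params(
      k = runif(1, 1e-3, 0.05), kd = runif(1, 0, 0.2),
      kf1 = runif(1, 0, 2e-3), kf_chain = runif(max(n - 1, 0), 0.01, 0.5),
      ks = runif(1, 0.01, 0.5), ki = runif(1, 0, 1e-3),
      kr = runif(1, 0, 0.1), n_intermediates = n,
      a0 = runif(1, 0.05, 2), p0 = runif(1, 5, 60),
      pf0 = runif(1, 0, 200), pi0 = runif(1, 0, 10), t_stress = 10)
    tr <- simulate_network(kp, t_grid)
    pools <- max(kp$a0 + kp$p0, kp$pf0, kp$pi0)
    expect_true(all(conservation_check(tr) < 1e-6 * pools))
    expect_true(all(tr$species > -1e-9))
  }
})

test_that("conservation audit flags a constructed violation by its exact size", {
  kp <- kinetic_params(k = 0.01, kd = 0.05, a0 = 0.5, p0 = 20, t_stress = 10)
  tr <- simulate_network(kp, seq(0, 60, 1))
  tr$species[30, "B"] <- tr$species[30, "B"] + 1
  drift <- conservation_check(tr)
  expect_equal(unname(drift["h2o2"]), 1, tolerance = 1e-6)
})

test_that("conservation laws hold exactly along Gillespie sample paths", {
  kp <- kinetic_params(k = 0.01, kd = 0.05, kf1 = 1e-3, kf_chain = 0.1,
                       ks = 0.1, ki = 5e-4, kr = 0.02, n_intermediates = 2L,
                       a0 = 1, p0 = 20, pf0 = 30, pi0 = 5, t_stress = 0)
  path <- ssa_simulate(kp, omega = 40, t_max = 40, seed = 7)
  expect_gt(nrow(path), 100)
  f_sum <- path[, "F1"] + path[, "F2"]
  p_consumed <- path[1, "P"] - path[, "P"]
  law1 <- path[, "A"] + path[, "B"] + f_sum + path[, "S"] + path[, "I"] +
    path[, "xF1"] - p_consumed - path[1, "A"]
  law2 <- path[, "pF"] + f_sum + path[, "S"] + path[, "xF1"] - path[1, "pF"]
  law3 <- path[, "pI"] + path[, "I"] + path[, "xF1"] - path[1, "pI"]
  expect_true(all(law1 == 0) && all(law2 == 0) && all(law3 == 0))
})

test_that("without inhibition SA release is monotone and bounded by the pF pool", {
  kp <- kinetic_params(k = 0.012, kd = 0.1, kf1 = 2e-3, ks = 0.1,
                       n_intermediates = 1L, a0 = 0.3, p0 = 40,
                       pf0 = 50, pi0 = 0, t_stress = 10)
  tr <- simulate_network(kp, seq(0, 400, 2))
  S <- tr$species[, "S"]
  expect_true(all(diff(S) > -1e-9))
  expect_lte(max(S), kp$pf0 + 1e-6)
})

test_that("secondary precursor injection restarts the burst without breaking the laws", {
  kp <- kinetic_params(k = 0.02, kd = 0.08, a0 = 0.3, p0 = 30,
                       t_stress = 10, t2 = 100, p2 = 15)
  t_grid <- seq(0, 200, 0.5)
  tr <- simulate_network(kp, t_grid)
  A <- tr$species[, "A"]
  # P jumps by p2 at t2 (post-injection value reported at the grid point)
  i2 <- which(t_grid == 100)
  expect_gt(tr$species[i2, "P"], tr$species[i2 - 1, "P"] + 0.9 * kp$p2)
  # a second local maximum appears after t2
  post2 <- t_grid > 100
  expect_gt(max(A[post2]), A[which(t_grid == 100)] + 1)
  expect_true(all(conservation_check(tr) < 1e-6 * (kp$a0 + kp$p0 + kp$p2)))
})

test_that("inhibitor pool and extra intermediates both delay SA onset", {
  onset_for <- function(pi0, n, total_delay = 30) {
    rates <- rep(n / total_delay, max(n - 1, 0))
    kp <- kinetic_params(k = 0.012, kd = 0.1, kf1 = 1e-3,
                         kf_chain = rates, ks = n / total_delay,
                         ki = 2e-3, kr = 0.1, n_intermediates = n,
                         a0 = 0.3, p0 = 40, pf0 = 100, pi0 = pi0,
                         t_stress = 10)
    tr <- simulate_network(kp, seq(0, 300, 1))
    onset_time(trajectory_series(tr, "S"))
  }
  # more inhibitor precursor never advances the onset
  ons_pi <- vapply(c(0, 2, 5, 10, 20), onset_for, numeric(1), n = 3L)
  expect_true(all(diff(ons_pi) >= 0))
  expect_gt(ons_pi[5], ons_pi[1])
  # more chain intermediates at fixed total throughput delays the onset
  ons_n <- vapply(1:5, function(n) onset_for(pi0 = 5, n = n), numeric(1))
  expect_true(all(diff(ons_n) >= 0))
  expect_gt(ons_n[5], ons_n[1])
})

test_that("invalid simulation inputs raise input errors", {
  expect_error(kinetic_params(k = -1, kd = 0.1, a0 = 1, p0 = 10),
               class = "phytowave_input_error")
  expect_error(kinetic_params(k = 0.01, kd = 0.1, a0 = 1, p0 = 10,
                              t_stress = 10, t2 = 5, p2 = 1),
               class = "phytowave_input_error")
  kp <- kinetic_params(k = 0.01, kd = 0.1, a0 = 1, p0 = 10, t_stress = 10)
  expect_error(simulate_network(kp, seq(20, 40, 1)),
               class = "phytowave_input_error")
})
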