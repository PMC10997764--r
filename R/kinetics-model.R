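#' Parameters of the stress-signaling reaction network
#'
#' The network couples an autocatalytic H2O2 (species A) burst to delayed
#' salicylic-acid (species S) release through a linear chain of biosynthetic
#' intermediates, with a generic inhibitor branch:
#' \itemize{
#'   \item A + P -> 2A (rate k): autocatalytic H2O2 production from an
#'     RBOH-like precursor pool P;
#'   \item A -> B (rate kd): H2O2 degradation;
#'   \item A + pF -> F1 (rate kf1): H2O2 activates the first SA precursor;
#'   \item F1 -> F2 -> ... -> Fn -> S (rates kf_chain, terminal ks): the
#'     intermediate chain releasing SA;
#'   \item A + pI -> I (rate ki): H2O2 produces an inhibitor;
#'   \item I + pF -> xF1 (rate kr): the inhibitor deactivates the SA
#'     precursor pool (xF1 is a dead end).
#' }
#' Stress is modeled as an instantaneous H2O2 seed a0 appearing at
#' \code{t_stress}; a secondary burst re-injects precursor p2 at \code{t2}.
#'
#' @param k autocatalysis rate, 1/(uM min).
#' @param kd H2O2 decay rate, 1/min.
#' @param kf1 A + pF activation rate, 1/(uM min).
#' @param kf_chain chain rates for F1 -> ... -> Fn transitions, 1/min;
#'   length \code{n_intermediates - 1} (the terminal step uses \code{ks}).
#' @param ks terminal SA-release rate, 1/min.
#' @param ki inhibitor-production rate, 1/(uM min).
#' @param kr inhibition/deactivation rate, 1/(uM min).
#' @param n_intermediates number of F species (1 to 6, default 3).
#' @param a0 initial H2O2 seed at stress, uM (> 0 for a stress run).
#' @param p0 initial precursor pool P, uM.
#' @param pf0 initial pF pool, uM.
#' @param pi0 initial pI pool, uM.
#' @param t_stress stress time, min.
#' @param t2 optional secondary-burst time, min (> t_stress).
#' @param p2 optional secondary precursor injection, uM.
#' @return object of class \code{kinetic_params}.
#' @export
kinetic_params <- function(k, kd, kf1 = 0, kf_chain = NULL, ks = 0,
                           ki = 0, kr = 0, n_intermediates = 3L,
                           a0, p0, pf0 = 0, pi0 = 0,
                           t_stress = 10, t2 = NULL, p2 = NULL) {
  n_intermediates <- as.integer(n_intermediates)
  if (n_intermediates < 1L || n_intermediates > 6L)
    stop_input("n_intermediates must be between 1 and 6")
  if (is.null(kf_chain)) kf_chain <- numeric(n_intermediates - 1L)
  if (length(kf_chain) != n_intermediates - 1L)
    stop_input("kf_chain must have length n_intermediates - 1")
  rates <- c(k = k, kd = kd, kf1 = kf1, ks = ks, ki = ki, kr = kr, kf_chain)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop_input("all rates must be finite and >= 0")
  pools <- c(a0 = a0, p0 = p0, pf0 = pf0, pi0 = pi0)
  if (any(!is.finite(pools)) || any(pools < 0))
    stop_input("all pools must be finite and >= 0")
  if (!is.null(t2)) {
    if (t2 <= t_stress) stop_input("t2 must be > t_stress")
    if (is.null(p2) || p2 < 0) stop_input("p2 must be >= 0 when t2 is set")
  }
  structure(list(k = k, kd = kd, kf1 = kf1, kf_chain = as.numeric(kf_chain),
                 ks = ks, ki = ki, kr = kr,
                 n_intermediates = n_intermediates,
                 a0 = a0, p0 = p0, pf0 = pf0, pi0 = pi0,
                 t_stress = t_stress, t2 = t2, p2 = p2),
            class = "kinetic_params")
}

#' @keywords internal
#' @noRd
species_names <- function(n) {
  c("A", "P", "B", "pF", paste0("F", seq_len(n)), "S", "pI", "I", "xF1")
}

#' @keywords internal
#' @noRd
network_rhs <- function(params) {
  n <- params$n_intermediates
  # transition rate out of F_j: chain rates, terminal step is ks
  out_rates <- c(params$kf_chain, params$ks)
  iF <- 4L + seq_len(n)   # indices of F1..Fn in the state vector
  iS <- 5L + n; ipI <- 6L + n; iI <- 7L + n; ixF <- 8L + n
  function(t, y, parms) {
    A <- y[1L]; P <- y[2L]; pF <- y[4L]
    pI <- y[ipI]; I <- y[iI]
    v_auto <- params$k * A * P
    v_dec  <- params$kd * A
    v_f1   <- params$kf1 * A * pF
    v_i    <- params$ki * A * pI
    v_r    <- params$kr * I * pF
    v_chain <- out_rates * y[iF]          # F_j -> F_{j+1} (or S)
    dy <- numeric(length(y))
    dy[1L] <- v_auto - v_dec - v_f1 - v_i
    dy[2L] <- -v_auto
    dy[3L] <- v_dec
    dy[4L] <- -v_f1 - v_r
    dy[iF[1L]] <- v_f1 - v_chain[1L]
    if (n > 1L) dy[iF[-1L]] <- v_chain[-n] - v_chain[-1L]
    dy[iS]  <- v_chain[n]
    dy[ipI] <- -v_i
    dy[iI]  <- v_i - v_r
    dy[ixF] <- v_r
    list(dy)
  }
}

#' Simulate the reaction network
#'
#' Integrates the mass-action ODE system with a stiff-capable solver
#' (\code{deSolve::lsoda}, rtol 1e-8, atol 1e-10). All species other than
#' the pools P, pF, pI are zero before \code{t_stress}; A jumps to a0 at
#' \code{t_stress}. When a secondary burst (t2, p2) is configured, the
#' integration is restarted at t2 with p2 added to P, so the discontinuity
#' never crosses a solver step.
#'
#' @param params a \code{\link{kinetic_params}}.
#' @param t_grid strictly increasing output times in minutes; must cover
#'   \code{t_stress}.
#' @param rtol,atol solver tolerances.
#' @return object of class \code{kinetic_trajectory}: list with
#'   \code{times}, \code{species} (matrix, one named column per species)
#'   and \code{params}.
#' @export
simulate_network <- function(params, t_grid, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "kinetic_params"))
  assert_increasing(t_grid, "t_grid")
  if (min(t_grid) > params$t_stress || max(t_grid) < params$t_stress)
    stop_input("t_grid must cover t_stress")
  n <- params$n_intermediates
  nm <- species_names(n)
  y_rest <- stats::setNames(numeric(length(nm)), nm)
  y_rest["P"] <- params$p0; y_rest["pF"] <- params$pf0; y_rest["pI"] <- params$pi0
  species <- matrix(NA_real_, nrow = length(t_grid), ncol = length(nm),
                    dimnames = list(NULL, nm))
  pre <- t_grid < params$t_stress
  if (any(pre)) species[pre, ] <- matrix(y_rest, sum(pre), length(nm), byrow = TRUE)

  rhs <- network_rhs(params)
  y0 <- y_rest; y0["A"] <- params$a0
  breaks <- c(params$t_stress, params$t2, max(t_grid, params$t_stress))
  breaks <- sort(unique(breaks[!is.null(breaks)]))
  y_cur <- y0
  for (s in seq_len(length(breaks) - 1L)) {
    t_lo <- breaks[s]; t_hi <- breaks[s + 1L]
    if (!is.null(params$t2) && isTRUE(all.equal(t_lo, params$t2)))
      y_cur["P"] <- y_cur["P"] + params$p2
    seg_pts <- t_grid[t_grid >= t_lo & t_grid <= t_hi]
    seg_times <- sort(unique(c(t_lo, seg_pts, t_hi)))
    if (length(seg_times) < 2L) { next }
    # capture.output: lsoda prints Fortran-level diagnostics on failed steps
    # (explosive parameter draws during fitting); failures are handled below
    utils::capture.output(
      sol <- deSolve::lsoda(y = y_cur, times = seg_times, func = rhs,
                            parms = NULL, rtol = rtol, atol = atol,
                            verbose = FALSE),
      type = "output")
    if (attr(sol, "istate")[1L] < 0)
      stop(structure(class = c("phytowave_integration_error", "error", "condition"),
                     list(message = "ODE integration failed", call = sys.call())))
    keep <- sol[, 1L] %in% seg_pts
    if (any(keep))
      species[match(sol[keep, 1L], t_grid), ] <- sol[keep, -1L, drop = FALSE]
    y_cur <- sol[nrow(sol), -1L]
  }
  # exact grid point at t_stress (post-jump value)
  at_stress <- which(t_grid == params$t_stress)
  if (length(at_stress)) species[at_stress, ] <- y0
  structure(list(times = t_grid, species = species, params = params),
            class = "kinetic_trajectory")
}

#' Stoichiometric conservation audit of a trajectory
#'
#' Three linear combinations of species are invariant under the network's
#' stoichiometry and are checked at every time point:
#' \enumerate{
#'   \item H2O2 bookkeeping: A + B + sum(F_i) + S + I + xF1 minus the
#'     precursor consumed (P_injected - P) minus the seed a0 (post-stress);
#'   \item SA-precursor pool: pF + sum(F_i) + S + xF1 = pf0;
#'   \item inhibitor-precursor pool: pI + I + xF1 = pi0.
#' }
#'
#' @param traj a \code{\link{kinetic_trajectory}}.
#' @param params the generating \code{\link{kinetic_params}} (defaults to
#'   the ones stored in the trajectory).
#' @return named numeric vector of maximal absolute drifts
#'   (h2o2, precursor_f, precursor_i), in uM.
#' @export
conservation_check <- function(traj, params = traj$params) {
  stopifnot(inherits(traj, "kinetic_trajectory"))
  sp <- traj$species
  n <- params$n_intermediates
  f_cols <- paste0("F", seq_len(n))
  f_sum <- rowSums(sp[, f_cols, drop = FALSE])
  post <- traj$times >= params$t_stress
  p_injected <- rep(params$p0, nrow(sp))
  if (!is.null(params$t2)) p_injected[traj$times >= params$t2] <-
    params$p0 + params$p2
  law1 <- sp[, "A"] + sp[, "B"] + f_sum + sp[, "S"] + sp[, "I"] + sp[, "xF1"] -
    (p_injected - sp[, "P"]) - params$a0 * as.numeric(post)
  law2 <- sp[, "pF"] + f_sum + sp[, "S"] + sp[, "xF1"] - params$pf0
  law3 <- sp[, "pI"] + sp[, "I"] + sp[, "xF1"] - params$pi0
  c(h2o2 = max(abs(law1)), precursor_f = max(abs(law2)),
    precursor_i = max(abs(law3)))
}

#' Extract a species time course as a concentration series
#'
#' @param traj a \code{\link{kinetic_trajectory}}.
#' @param species species name, e.g. "A" or "S".
#' @return a \code{\link{concentration_series}}.
#' @export
trajectory_series <- function(traj, species = "A") {
  stopifnot(inherits(traj, "kinetic_trajectory"),
            species %in% colnames(traj$species))
  concentration_series(times = traj$times,
                       values = traj$species[, species],
                       t_stress = traj$params$t_stress)
}

#' Write a trajectory as CSV (time_min plus one column per species)
#'
#' @param traj a \code{\link{kinetic_trajectory}}.
#' @param path file path.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- data.frame(time_min = traj$times, traj$species, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
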