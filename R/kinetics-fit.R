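#' @keywords internal
#' @noRd
params_to_vector <- function(params) {
  v <- c(k = params$k, kd = params$kd, kf1 = params$kf1, ks = params$ks,
         ki = params$ki, kr = params$kr, a0 = params$a0, p0 = params$p0,
         pf0 = params$pf0, pi0 = params$pi0)
  if (params$n_intermediates > 1L) {
    ch <- params$kf_chain
    names(ch) <- paste0("kf_chain", seq_along(ch))
    v <- c(v, ch)
  }
  if (!is.null(params$t2)) v <- c(v, t2 = params$t2, p2 = params$p2)
  v
}

#' @keywords internal
#' @noRd
vector_to_params <- function(v, template) {
  ch_names <- paste0("kf_chain", seq_len(template$n_intermediates - 1L))
  kinetic_params(
    k = v[["k"]], kd = v[["kd"]], kf1 = v[["kf1"]],
    kf_chain = if (length(ch_names)) unname(v[ch_names]) else NULL,
    ks = v[["ks"]], ki = v[["ki"]], kr = v[["kr"]],
    n_intermediates = template$n_intermediates,
    a0 = v[["a0"]], p0 = v[["p0"]], pf0 = v[["pf0"]], pi0 = v[["pi0"]],
    t_stress = template$t_stress,
    t2 = if ("t2" %in% names(v)) v[["t2"]] else template$t2,
    p2 = if ("p2" %in% names(v)) v[["p2"]] else template$p2)
}

#' Fit the reaction network to measured H2O2 and SA series
#'
#' Minimizes the weighted sum of squares
#' w_A * sum((A_model - A_obs)^2) + w_S * sum((S_model - S_obs)^2)
#' over the non-frozen parameters, with weights equal to the inverse
#' squared series maxima so the uM-scale disparity between the H2O2 and SA
#' channels does not let one dominate (a series with zero maximum gets
#' weight 0). Free parameters are optimized in log space (all rates and
#' pools are positive) by Levenberg-Marquardt from Latin-hypercube
#' perturbations of the initial guess.
#'
#' @param h2o2 a \code{\link{concentration_series}} of measured H2O2 (uM).
#' @param sa a \code{\link{concentration_series}} of measured SA (uM),
#'   sharing the time origin with \code{h2o2}.
#' @param init initial \code{\link{kinetic_params}}.
#' @param frozen character vector of parameter names held at their init
#'   values (e.g. c("kf1", "ks")). Parameters whose init value is 0 are
#'   always frozen (log-space optimization cannot leave 0).
#' @param n_starts Latin-hypercube multistarts, default 16 (the first
#'   start is the unperturbed init).
#' @param perturb multiplicative perturbation range for the multistarts,
#'   default c(0.5, 2).
#' @param seed RNG seed for the hypercube, default 0.
#' @param maxiter Levenberg-Marquardt iteration cap per start.
#' @return object of class \code{kinetic_fit}: list with \code{params},
#'   \code{residual_h2o2}, \code{residual_sa} (model minus observed, on
#'   the observation grids), \code{sse}, \code{converged}.
#' @export
fit_kinetic_model <- function(h2o2, sa, init, frozen = character(),
                              n_starts = 16L, perturb = c(0.5, 2),
                              seed = 0L, maxiter = 100L) {
  stopifnot(inherits(h2o2, "concentration_series"),
            inherits(sa, "concentration_series"),
            inherits(init, "kinetic_params"))
  v0 <- params_to_vector(init)
  frozen <- union(frozen, names(v0)[v0 == 0])
  free <- setdiff(names(v0), frozen)
  if (!length(free)) stop_input("no free parameters to fit")

  w_a <- if (max(h2o2$values) > 0) 1 / max(h2o2$values)^2 else 0
  w_s <- if (max(sa$values) > 0) 1 / max(sa$values)^2 else 0
  t_eval <- sort(unique(c(h2o2$times, sa$times, init$t_stress)))

  residuals_for <- function(v) {
    p <- vector_to_params(v, init)
    traj <- simulate_network(p, t_eval, rtol = 1e-7, atol = 1e-9)
    a_mod <- traj$species[match(h2o2$times, t_eval), "A"]
    s_mod <- traj$species[match(sa$times, t_eval), "S"]
    list(a = a_mod - h2o2$values, s = s_mod - sa$values)
  }
  weighted_resid <- function(logfree) {
    v <- v0
    v[free] <- exp(logfree)
    r <- tryCatch(residuals_for(v), error = function(e) NULL)
    if (is.null(r)) return(rep(1e6, length(h2o2$values) + length(sa$values)))
    c(sqrt(w_a) * r$a, sqrt(w_s) * r$s)
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)
  starts <- matrix(0, n_starts, length(free))
  if (n_starts > 1L) {
    lh <- lhs::randomLHS(n_starts - 1L, length(free))
    starts[-1L, ] <- log(perturb[1L]) + lh * (log(perturb[2L]) - log(perturb[1L]))
  }
  base <- log(v0[free])

  best <- NULL
  for (s in seq_len(n_starts)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = base + starts[s, ], fn = weighted_resid,
                         control = minpack.lm::nls.lm.control(maxiter = maxiter)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(weighted_resid(fit$par)^2)
    conv <- fit$info %in% 1:4
    if (is.null(best) || sse < best$sse)
      best <- list(par = fit$par, sse = sse, converged = conv)
  }
  if (is.null(best))
    return(structure(list(params = init, residual_h2o2 = NULL,
                          residual_sa = NULL, sse = Inf, converged = FALSE),
                     class = "kinetic_fit"))
  v <- v0
  v[free] <- exp(best$par)
  p_fit <- vector_to_params(v, init)
  r <- residuals_for(v)
  structure(list(params = p_fit,
                 residual_h2o2 = data.frame(time_min = h2o2$times, residual = r$a),
                 residual_sa = data.frame(time_min = sa$times, residual = r$s),
                 sse = best$sse, converged = best$converged),
            class = "kinetic_fit")
}

#' Serialize kinetic parameters or a fit result as JSON
#'
#' @param x a \code{\link{kinetic_params}} or \code{kinetic_fit}.
#' @param path file path.
#' @export
write_kinetics_json <- function(x, path) {
  if (inherits(x, "kinetic_fit")) {
    out <- list(params = unclass(x$params), sse = x$sse,
                converged = x$converged)
  } else out <- unclass(x)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
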