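# Independent oracles, written against the reaction list itself rather than
# the package's hand-coded derivative, so the two routes can disagree.

# reaction table: each entry has a propensity function of the named state
# and an integer stoichiometry vector over the species
oracle_reactions <- function(params) {
  n <- params$n_intermediates
  nm <- c("A", "P", "B", "pF", paste0("F", seq_len(n)), "S", "pI", "I", "xF1")
  zero <- stats::setNames(integer(length(nm)), nm)
  sv <- function(...) { v <- zero; ch <- list(...)
    for (s in names(ch)) v[s] <- ch[[s]]; v }
  out_rates <- c(params$kf_chain, params$ks)
  rx <- list(
    list(rate = function(y) params$k * y["A"] * y["P"],
         stoich = sv(A = +1, P = -1)),
    list(rate = function(y) params$kd * y["A"],
         stoich = sv(A = -1, B = +1)),
    list(rate = function(y) params$kf1 * y["A"] * y["pF"],
         stoich = sv(A = -1, pF = -1, F1 = +1)),
    list(rate = function(y) params$ki * y["A"] * y["pI"],
         stoich = sv(A = -1, pI = -1, I = +1)),
    list(rate = function(y) params$kr * y["I"] * y["pF"],
         stoich = sv(I = -1, pF = -1, xF1 = +1)))
  for (j in seq_len(n)) {
    local({
      jj <- j
      from <- paste0("F", jj)
      to <- if (jj < n) paste0("F", jj + 1L) else "S"
      st <- zero; st[from] <- -1L; st[to] <- +1L
      rx[[length(rx) + 1L]] <<- list(
        rate = function(y) out_rates[jj] * y[from], stoich = st)
    })
  }
  list(reactions = rx, species = nm)
}

oracle_rhs <- function(params) {
  tab <- oracle_reactions(params)
  function(y) {
    dy <- stats::setNames(numeric(length(y)), names(y))
    for (r in tab$reactions) dy <- dy + r$rate(y) * r$stoich
    dy
  }
}

# fixed-step classical RK4 over [t0, t1], returning states at output_times
rk4_integrate <- function(params, t0, t1, y0, dt = 1e-3, output_times = NULL) {
  f <- oracle_rhs(params)
  if (is.null(output_times)) output_times <- c(t0, t1)
  out <- matrix(NA_real_, length(output_times), length(y0),
                dimnames = list(NULL, names(y0)))
  y <- y0; t <- t0
  oi <- which(abs(output_times - t0) < 1e-12)
  if (length(oi)) out[oi, ] <- y
  n_steps <- ceiling((t1 - t0) / dt)
  next_out <- which(output_times > t0 + 1e-12)
  for (s in seq_len(n_steps)) {
    h <- min(dt, t1 - t)
    k1 <- f(y); k2 <- f(y + h / 2 * k1); k3 <- f(y + h / 2 * k2)
    k4 <- f(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + h
    hit <- next_out[abs(output_times[next_out] - t) < dt / 2]
    if (length(hit)) { out[hit, ] <- matrix(y, length(hit), length(y),
                                            byrow = TRUE)
      next_out <- setdiff(next_out, hit) }
    if (t >= t1 - 1e-12) break
  }
  out
}

# Gillespie stochastic simulation over the same reaction list, in integer
# copy numbers (volume scaling omega converts uM pools to counts)
ssa_simulate <- function(params, omega = 50, t_max = 60, max_events = 20000,
                         seed = 1) {
  set.seed(seed)
  tab <- oracle_reactions(params)
  nm <- tab$species
  y <- stats::setNames(numeric(length(nm)), nm)
  y["A"] <- round(params$a0 * omega); y["P"] <- round(params$p0 * omega)
  y["pF"] <- round(params$pf0 * omega); y["pI"] <- round(params$pi0 * omega)
  # propensities: bimolecular rates scale 1/omega in count units
  order2 <- c(TRUE, FALSE, TRUE, TRUE, TRUE,
              rep(FALSE, params$n_intermediates))
  t <- 0; path <- list(y)
  for (ev in seq_len(max_events)) {
    a <- vapply(seq_along(tab$reactions), function(i) {
      r <- tab$reactions[[i]]$rate(y)
      if (order2[i]) r / omega else r
    }, numeric(1))
    a_tot <- sum(a)
    if (a_tot <= 0) break
    t <- t + stats::rexp(1, a_tot)
    if (t > t_max) break
    i <- sample.int(length(a), 1L, prob = a)
    y <- y + tab$reactions[[i]]$stoich
    path[[length(path) + 1L]] <- y
  }
  do.call(rbind, path)
}

# brute-force FWHM: dense linear interpolation, exhaustive scan of all
# half-level crossings, crossing nearest the peak on each side
fwhm_bruteforce <- function(times, values, t_stress, n_dense = 200001L) {
  pre <- times < t_stress
  base <- if (any(pre)) mean(values[pre]) else 0
  tt <- seq(min(times), max(times), length.out = n_dense)
  vv <- stats::approx(times, values, tt)$y
  post <- tt >= t_stress
  pk <- which(post)[which.max(vv[post])]
  half <- base + (vv[pk] - base) / 2
  above <- vv >= half
  cross <- which(diff(above) != 0)
  left <- cross[cross < pk]; right <- cross[cross >= pk]
  tt[min(right)] - tt[max(left)]
}
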