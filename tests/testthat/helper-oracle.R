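# Independent reference implementation of the network dynamics, coded
# directly from the printed state equations as plain scalar R and integrated
# with deSolve's adaptive solver. Used as a brute-force oracle for the
# package's compiled fixed-step integrator; shares no code with it.

oracle_rhs <- function(t, x, p) {
  n <- p$n
  xv <- matrix(x[1:(4 * n)], 4, n)
  xi <- matrix(x[4 * n + 1:(4 * n)], 4, n)
  d <- 1 / (1 + exp(-p$r * (xv - p$v0))) - 0.5
  dxv <- xi
  dxi <- matrix(0, 4, n)
  for (i in seq_len(n)) {
    fwd <- 0; bwd <- 0; lat <- 0
    for (j in seq_len(n)) {
      fwd <- fwd + p$Afwd[i, j] * d[1, j]   # SP output of source j
      bwd <- bwd + p$Abwd[i, j] * d[3, j]   # DP output of source j
      lat <- lat + p$Alat[i, j] * d[1, j]
    }
    e <- p$exo_amp[i] * exp(-0.5 * ((t - p$exo_onset[i]) / p$exo_width[i])^2)
    U <- c(bwd, fwd + lat + e, fwd + lat, bwd) + drop(p$G[[i]] %*% d[, i])
    dxi[, i] <- p$K[, i] * U - 2 * p$K[, i] * xi[, i] - p$K[, i]^2 * xv[, i]
  }
  list(c(as.numeric(dxv), as.numeric(dxi)))
}

oracle_simulate <- function(p, obs_J, obs_L, tspan = c(-100, 300), fs = 500) {
  times <- seq(tspan[1], tspan[2], by = 1000 / fs)
  sol <- deSolve::ode(y = rep(0, 8 * p$n), times = times, func = oracle_rhs,
                      parms = p, method = "ode45",
                      rtol = 1e-9, atol = 1e-10)
  y <- matrix(0, p$n, length(times))
  for (k in seq_along(times)) {
    xv <- matrix(sol[k, 1 + 1:(4 * p$n)], 4, p$n)
    y[, k] <- obs_L * colSums(obs_J * xv)
  }
  list(y = y, time = times)
}

# package architecture -> oracle parameter list
oracle_params_from <- function(arch, params = cmc_node_params(),
                               coupling = default_coupling(arch),
                               exo = exogenous_input()) {
  n <- length(arch$nodes)
  amp <- arch$C * exo$amplitude
  onset <- rep(exo$onset, n)
  if (any(arch$latent > 0)) {
    amp <- amp + arch$latent * exo$latent_amplitude
    onset[arch$latent > 0] <- exo$latent_onset
  }
  list(n = n,
       K = vapply(seq_len(n), function(i) params$K, numeric(4)),
       G = rep(list(params$G), n),
       Afwd = coupling$fwd, Abwd = coupling$bwd, Alat = coupling$lat,
       r = params$r, v0 = params$v0,
       exo_amp = amp, exo_onset = onset, exo_width = rep(exo$width, n))
}
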