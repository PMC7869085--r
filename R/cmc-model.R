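#' Canonical-microcircuit node parameters
#'
#' One cortical column is modelled as four interacting neural populations:
#' superficial pyramidal cells (SP), granular spiny stellate cells (SS), deep
#' pyramidal cells (DP) and inhibitory interneurons (II). Each population has
#' a membrane voltage and current obeying second-order dynamics
#' \deqn{\dot x_v = x_i, \qquad \dot x_i = K U - 2 K x_i - K^2 x_v}
#' where `K` is the population rate constant (1/ms) and `U` collects
#' intrinsic, extrinsic and exogenous drive.
#'
#' The intrinsic coupling matrix `G` (rows = target population, columns =
#' source) follows the standard canonical-microcircuit wiring: excitatory
#' SS->SP, SS->II and DP->II connections, inhibitory SP->SS, II->SS and
#' II->DP connections, and inhibitory self-gain (decay) terms on every
#' population. Self-gain entries must be negative.
#'
#' @param K Named positive rate constants (1/ms) for SP, SS, DP, II.
#'   Defaults correspond to membrane time constants of 2, 2, 28 and 16 ms.
#' @param G 4x4 signed intrinsic coupling matrix (unitless gains).
#' @param r Sigmoid slope of the firing-rate nonlinearity (1/mV).
#' @param v0 Sigmoid threshold voltage (mV).
#' @return An object of class `cmc_node_params`.
#' @export
cmc_node_params <- function(K = c(SP = 1/2, SS = 1/2, DP = 1/28, II = 1/16),
                            G = cmc_default_G(),
                            r = 2/3, v0 = 0) {
  pops <- cmc_populations()
  K <- K[pops]
  if (any(!is.finite(K)) || any(K <= 0))
    stop("rate constants K must be positive and finite for all 4 populations")
  if (!is.matrix(G) || any(dim(G) != 4))
    stop("G must be a 4x4 matrix over populations ", paste(pops, collapse = ", "))
  dimnames(G) <- list(pops, pops)
  if (any(diag(G) >= 0))
    stop("self-gain (diagonal) entries of G must be negative (inhibitory decay)")
  structure(list(K = K, G = G, r = r, v0 = v0), class = "cmc_node_params")
}

#' Default intrinsic coupling matrix of the canonical microcircuit
#'
#' Rows index the target population, columns the source. Signs encode the
#' polarity classes of the microcircuit (excitatory ascending SS drive,
#' inhibitory interneuron output, inhibitory self-gain on every population);
#' magnitudes follow the conventional 8:4:2:1 relative weighting of the
#' published circuit, at a base scale chosen for a damped, oscillatory
#' impulse response.
#' @return 4x4 numeric matrix.
#' @export
cmc_default_G <- function() {
  pops <- cmc_populations()
  G <- matrix(0, 4, 4, dimnames = list(pops, pops))
  G["SP", "SP"] <- -8;  G["SP", "SS"] <- +8
  G["SS", "SP"] <- -8;  G["SS", "SS"] <- -16; G["SS", "II"] <- -8
  G["DP", "DP"] <- -2;  G["DP", "II"] <- -4
  G["II", "SS"] <- +8;  G["II", "DP"] <- +4;  G["II", "II"] <- -16
  G
}

#' Population state of one node
#'
#' @param x_v Named voltages (mV) for SP, SS, DP, II.
#' @param x_i Named currents (mV/ms).
#' @return Object of class `population_state`.
#' @export
population_state <- function(x_v = numeric(4), x_i = numeric(4)) {
  pops <- cmc_populations()
  x_v <- setNames(rep_len(x_v, 4), pops)
  x_i <- setNames(rep_len(x_i, 4), pops)
  structure(list(x_v = x_v, x_i = x_i), class = "population_state")
}

#' Presynaptic firing via the centred sigmoid
#'
#' Mean-field firing of a population given its membrane depolarisation:
#' a logistic function centred so that firing is exactly zero at the
#' threshold `v0`, which places the network fixed point at the origin.
#'
#' @param v Membrane voltage(s), mV.
#' @param params A [cmc_node_params()] object supplying slope `r` and
#'   threshold `v0`.
#' @return Firing values in (-1/2, 1/2), same shape as `v`.
#' @export
sigmoid_firing <- function(v, params = cmc_node_params()) {
  if (any(!is.finite(v))) stop("non-finite membrane voltage")
  1 / (1 + exp(-params$r * (v - params$v0))) - 0.5
}

#' Time derivative of one node's populations
#'
#' Implements \eqn{\dot x_v = x_i}, \eqn{\dot x_i = K U - 2K x_i - K^2 x_v}
#' with \eqn{U = S d + H + E}: `afferent` is the extrinsic drive `S d`
#' already resolved per population, `H = G d` is computed here from the
#' node's own firing, and `exo` is exogenous input.
#'
#' @param state A [population_state()].
#' @param afferent Extrinsic drive per population (length 4, or scalar 0).
#' @param exo Exogenous drive per population (length 4, or scalar 0).
#' @param params A [cmc_node_params()].
#' @return A `population_state` holding the derivatives.
#' @export
node_derivative <- function(state, afferent = 0, exo = 0,
                            params = cmc_node_params()) {
  if (!inherits(state, "population_state")) stop("state must be a population_state")
  afferent <- .conform4(afferent, "afferent")
  exo <- .conform4(exo, "exo")
  d <- sigmoid_firing(state$x_v, params)
  H <- drop(params$G %*% d)
  U <- afferent + H + exo
  K <- params$K
  population_state(x_v = state$x_i,
                   x_i = K * U - 2 * K * state$x_i - K^2 * state$x_v)
}

.conform4 <- function(x, what) {
  if (length(x) == 1L) return(rep(x, 4))
  if (length(x) != 4L)
    stop(sprintf("%s must have one entry per population (4), got %d",
                 what, length(x)))
  x
}

#' Observation (forward) model parameters
#'
#' The virtual-electrode signal of each node is a gain-scaled, laminar-
#' weighted mixture of its population voltages, `y = L x J`. By default only
#' three contribution weights per node are nonzero (SP 0.8, SS 0.2, DP 0.2,
#' II 0) and homologous left/right nodes share identical J vectors.
#'
#' @param L Positive electrode gain per node.
#' @param J 4 x n matrix of contribution weights (rows = populations).
#' @param noise_sd Observation noise standard deviation (signal units).
#' @param nodes Node labels.
#' @return Object of class `observation_params`.
#' @export
observation_params <- function(L = NULL, J = NULL, noise_sd = 0,
                               nodes = cmc_nodes()) {
  n <- length(nodes)
  if (is.null(L)) L <- rep(1, n)
  if (is.null(J))
    J <- matrix(c(0.8, 0.2, 0.2, 0), 4, n,
                dimnames = list(cmc_populations(), nodes))
  if (any(L < 0)) stop("electrode gains L must be non-negative")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (!all(dim(J) == c(4, n))) stop("J must be 4 x n_nodes")
  dimnames(J) <- list(cmc_populations(), nodes)
  structure(list(L = setNames(L, nodes), J = J, noise_sd = noise_sd,
                 nodes = nodes),
            class = "observation_params")
}

#' Exogenous input waveform
#'
#' A smooth Gaussian bump driving the granular layer (SS, "layer 4") of the
#' input nodes. Sensory input targets bilateral A1; architectures with a
#' top-down latent input additionally drive rIFG with the same waveform
#' class at its own onset.
#'
#' @param onset Bump centre for the sensory input (ms post stimulus).
#' @param width Bump standard deviation (ms).
#' @param amplitude Input amplitude (unitless).
#' @param latent_onset Bump centre for the latent (top-down) input, ms.
#' @param latent_amplitude Amplitude of the latent input.
#' @return Object of class `exogenous_input`.
#' @export
exogenous_input <- function(onset = 60, width = 16, amplitude = 4,
                            latent_onset = 120, latent_amplitude = 4) {
  stopifnot(width > 0)
  structure(list(onset = onset, width = width, amplitude = amplitude,
                 latent_onset = latent_onset,
                 latent_amplitude = latent_amplitude),
            class = "exogenous_input")
}

# per-node SS drive of the exogenous input at time t (ms)
exo_drive_at <- function(exo, arch, t) {
  bump <- function(a, mu) a * exp(-0.5 * ((t - mu) / exo$width)^2)
  drv <- arch$C * bump(exo$amplitude, exo$onset)
  if (any(arch$latent > 0))
    drv <- drv + arch$latent * bump(exo$latent_amplitude, exo$latent_onset)
  drv
}

#' Default extrinsic coupling gains for an architecture
#'
#' Prior-mean gain for every edge present in the adjacency matrices.
#' Forward gains default to 6, backward and lateral to 3 (unitless drive per
#' unit presynaptic firing).
#' @param arch A [network_architecture()].
#' @param fwd,bwd,lat Gain applied to each edge class.
#' @return List of three n x n gain matrices (`fwd`, `bwd`, `lat`).
#' @export
default_coupling <- function(arch, fwd = 6, bwd = 3, lat = 3) {
  list(fwd = arch$A_fwd * fwd, bwd = arch$A_bwd * bwd, lat = arch$A_lat * lat)
}

#' Full-network state derivative
#'
#' Assembles extrinsic drive according to the laminar projection rules
#' (forward edges carry SP firing to target SS and DP; backward edges carry
#' DP firing to target SP and II; lateral edges carry SP firing to SS and
#' DP), adds exogenous input to SS of input-flagged nodes, and applies
#' [node_derivative()] per node.
#'
#' @param states List of [population_state()], one per node.
#' @param arch A [network_architecture()].
#' @param params A single [cmc_node_params()] shared by all nodes, or a list
#'   of one per node.
#' @param coupling List of gain matrices as from [default_coupling()].
#' @param exo Either an [exogenous_input()] (evaluated at `t`) or a numeric
#'   vector of per-node SS drive.
#' @param t Time (ms) at which to evaluate exogenous input.
#' @return List of `population_state` derivatives, one per node.
#' @export
network_derivative <- function(states, arch, params = cmc_node_params(),
                               coupling = default_coupling(arch),
                               exo = 0, t = 0) {
  n <- length(arch$nodes)
  if (length(states) != n) stop("need one population_state per node")
  if (inherits(params, "cmc_node_params")) params <- rep(list(params), n)
  if (any(dim(coupling$fwd) != n)) stop("coupling matrices must be n x n")
  if (inherits(exo, "exogenous_input")) exo <- exo_drive_at(exo, arch, t)
  exo <- rep_len(exo, n)

  dSP <- vapply(seq_len(n), function(i)
    sigmoid_firing(states[[i]]$x_v[["SP"]], params[[i]]), numeric(1))
  dDP <- vapply(seq_len(n), function(i)
    sigmoid_firing(states[[i]]$x_v[["DP"]], params[[i]]), numeric(1))

  fwd <- drop(coupling$fwd %*% dSP)
  bwd <- drop(coupling$bwd %*% dDP)
  lat <- drop(coupling$lat %*% dSP)

  lapply(seq_len(n), function(i) {
    aff <- c(SP = bwd[i], SS = fwd[i] + lat[i], DP = fwd[i] + lat[i],
             II = bwd[i])
    node_derivative(states[[i]], afferent = aff,
                    exo = c(0, exo[i], 0, 0), params = params[[i]])
  })
}

#' Project hidden states to virtual-electrode signals
#'
#' `y = L x J`: per node, the gain-scaled, J-weighted sum of population
#' voltages. Linear (and homogeneous) in the states.
#'
#' @param states A 4 x n matrix of population voltages (rows SP, SS, DP,
#'   II), or a 4 x n x T array over time.
#' @param obs An [observation_params()].
#' @return Numeric vector (length n) or n x T matrix of signals.
#' @export
project_observation <- function(states, obs = observation_params()) {
  if (any(obs$L < 0)) stop("electrode gains L must be non-negative")
  proj1 <- function(m) obs$L * colSums(obs$J * m)
  if (is.matrix(states)) return(proj1(states))
  if (length(dim(states)) == 3) {
    out <- apply(states, 3, proj1)
    rownames(out) <- obs$nodes
    return(out)
  }
  stop("states must be a 4 x n matrix or 4 x n x T array")
}

#' Simulate a noiseless evoked response for one condition
#'
#' Integrates the coupled canonical-microcircuit network over the
#' peristimulus window with a fixed-step 4th-order Runge-Kutta scheme,
#' starting at the origin fixed point, and projects the hidden voltages
#' through the observation model. Output is sampled at `fs` Hz.
#'
#' @param arch A [network_architecture()].
#' @param params A [cmc_node_params()] shared across nodes, or list per node.
#' @param obs An [observation_params()].
#' @param exo An [exogenous_input()].
#' @param coupling Extrinsic gain matrices, see [default_coupling()].
#' @param tspan Peristimulus window in ms, default -100..300.
#' @param dt Integration step (ms); must divide the output sample period.
#' @param fs Output sampling rate (Hz).
#' @param return_states Also return the population voltages over time.
#' @return List with `y` (n_nodes x n_samples signal matrix), `time` (ms),
#'   `fs`, and optionally `states` (4 x n x T). An error is signalled, with
#'   the divergence time, if the states blow up.
#' @export
simulate_erp <- function(arch, params = cmc_node_params(),
                         obs = observation_params(nodes = arch$nodes),
                         exo = exogenous_input(),
                         coupling = default_coupling(arch),
                         tspan = c(-100, 300), dt = 1, fs = 500,
                         return_states = FALSE) {
  stopifnot(dt > 0, diff(tspan) > 0)
  period <- 1000 / fs
  record_every <- period / dt
  if (abs(record_every - round(record_every)) > 1e-9)
    stop("integration step dt must divide the output sample period 1000/fs")
  record_every <- as.integer(round(record_every))

  n <- length(arch$nodes)
  if (inherits(params, "cmc_node_params")) params <- rep(list(params), n)
  K <- vapply(params, function(p) p$K, numeric(4))
  Gc <- array(0, c(4, 4, n))
  for (i in seq_len(n)) Gc[, , i] <- params[[i]]$G

  amp <- arch$C * exo$amplitude
  onset <- rep(exo$onset, n)
  if (any(arch$latent > 0)) {
    amp <- amp + arch$latent * exo$latent_amplitude
    onset[arch$latent > 0] <- exo$latent_onset
  }

  res <- simulate_cmc_cpp(K, Gc, coupling$fwd, coupling$bwd, coupling$lat,
                          amp, onset, rep(exo$width, n),
                          obs$J, unname(obs$L),
                          params[[1]]$r, params[[1]]$v0,
                          tspan[1], tspan[2], dt, record_every, return_states)
  if (!is.na(res$diverged_at))
    stop(sprintf("numerically unstable parameter set: states diverged at t = %.1f ms",
                 res$diverged_at))
  rownames(res$y) <- arch$nodes
  out <- list(y = res$y, time = drop(res$time), fs = fs, nodes = arch$nodes)
  if (return_states) out$states <- res$states
  out
}

#' Default priors of the generative and observation model
#'
#' Returns the documented prior means of the node, observation and input
#' parameters, together with the prior log-scaling variances used by the
#' inversion (all free parameters are log-scaling factors around these
#' means, with prior mean 0).
#'
#' @return List with elements `node` ([cmc_node_params()]), `obs`
#'   ([observation_params()]; J prior SP = 0.8, SS = 0.2, DP = 0.2, II = 0
#'   per node, hemisphere-symmetric), `exo` ([exogenous_input()]), `gains`
#'   (prior extrinsic gains per edge class), and `variances` (prior
#'   log-scaling variance per parameter block).
#' @export
default_priors <- function() {
  list(node = cmc_node_params(),
       obs = observation_params(),
       exo = exogenous_input(),
       gains = c(fwd = 6, bwd = 3, lat = 3),
       variances = c(A = 1/8, B = 1/8, J = 1/16, L = 1/16, G = 1/16))
}
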