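#' Prior specification over log-scaling parameters
#'
#' Every estimable quantity of the generative pair is parameterised as a
#' log-scaling factor around its prior mean (prior mean 0 = the underlying
#' quantity at its prior value), so positivity constraints hold by
#' construction. Parameter blocks:
#' \describe{
#'   \item{A}{one gain per extrinsic edge (forward/backward/lateral)}
#'   \item{B}{condition (deviant) gain modulations, one shared parameter for
#'     the modulated extrinsic edges and one for the modulated SP
#'     self-gains}
#'   \item{J}{laminar contribution weights, hemisphere-tied: one parameter
#'     per region pair (A1, STG, IFG) and population (SP, SS, DP)}
#'   \item{L}{electrode gain per node}
#'   \item{G}{intrinsic self-gain scalings, hemisphere-tied: one per region
#'     pair and population}
#' }
#' Blocks not listed in `free` are fixed (prior variance 0) and never move
#' during inversion.
#'
#' @param arch A [network_architecture()].
#' @param free Character vector of free parameter blocks.
#' @param base Prior means and block variances, see [default_priors()].
#' @return Object of class `prior_spec`: a parameter table (`table`) with
#'   name, block, prior mean and variance, plus the architecture and base
#'   quantities needed to realize a simulation from a parameter vector.
#' @export
cmc_priors <- function(arch, free = c("A", "B", "J", "L"),
                       base = default_priors()) {
  stopifnot(inherits(arch, "network_architecture"))
  nodes <- arch$nodes
  region <- sub("^[lr]", "", nodes)
  v <- base$variances

  rows <- list()
  add <- function(name, block, var)
    rows[[length(rows) + 1L]] <<- data.frame(name = name, block = block,
                                             mean = 0, var = var)
  edge_names <- function(A, cls) {
    idx <- which(A != 0, arr.ind = TRUE)
    if (nrow(idx) == 0) return(character(0))
    sprintf("A.%s.%s>%s", cls, nodes[idx[, "col"]], nodes[idx[, "row"]])
  }
  for (cls in c("fwd", "bwd", "lat"))
    for (nm in edge_names(arch[[paste0("A_", cls)]], cls))
      add(nm, "A", if ("A" %in% free) v[["A"]] else 0)

  has_ext_mod <- any(arch$B_fwd != 0) || any(arch$B_bwd != 0) ||
    any(arch$B_lat != 0)
  if (has_ext_mod)
    add("B.extrinsic", "B", if ("B" %in% free) v[["B"]] else 0)
  if (any(arch$B_self))
    add("B.self", "B", if ("B" %in% free) v[["B"]] else 0)

  for (reg in unique(region))
    for (p in c("SP", "SS", "DP"))
      add(sprintf("J.%s.%s", reg, p), "J", if ("J" %in% free) v[["J"]] else 0)
  for (nd in nodes)
    add(sprintf("L.%s", nd), "L", if ("L" %in% free) v[["L"]] else 0)
  for (reg in unique(region))
    for (p in cmc_populations())
      add(sprintf("G.%s.%s", reg, p), "G", if ("G" %in% free) v[["G"]] else 0)

  tab <- do.call(rbind, rows)
  rownames(tab) <- tab$name
  out <- structure(list(table = tab, arch = arch, base = base,
                        free = free, nodes = nodes, region = region),
                   class = "prior_spec")
  out$fast <- .build_fast(out)
  out
}

# precomputed index maps from the parameter vector into simulator inputs,
# so that repeated predictions (Jacobians) avoid per-call bookkeeping
.build_fast <- function(priors) {
  arch <- priors$arch
  base <- priors$base
  nodes <- arch$nodes
  region <- priors$region
  n <- length(nodes)
  nm <- priors$table$name
  ti <- function(x) match(x, nm)

  Gbase <- array(rep(base$node$G, n), c(4, 4, n))
  pops <- cmc_populations()
  g_lin <- integer(0); g_tidx <- integer(0); g_sp <- logical(0)
  for (i in seq_len(n)) for (p in 1:4) {
    g_lin <- c(g_lin, (i - 1) * 16 + (p - 1) * 4 + p)
    g_tidx <- c(g_tidx, ti(sprintf("G.%s.%s", region[i], pops[p])))
    g_sp <- c(g_sp, arch$B_self[[i]] && pops[p] == "SP")
  }

  cp <- list()
  for (cls in c("fwd", "bwd", "lat")) {
    A <- arch[[paste0("A_", cls)]]
    Bm <- arch[[paste0("B_", cls)]]
    Mb <- A * base$gains[[cls]]
    idx <- which(A != 0)
    ij <- which(A != 0, arr.ind = TRUE)
    tn <- if (length(idx)) ti(sprintf("A.%s.%s>%s", cls,
                                      nodes[ij[, "col"]], nodes[ij[, "row"]]))
          else integer(0)
    cp[[cls]] <- list(Mb = Mb, lin = idx, tidx = tn,
                      bflag = as.logical(Bm[idx]))
  }

  Jbase <- base$obs$J
  colnames(Jbase) <- nodes
  j_lin <- integer(0); j_tidx <- integer(0)
  for (i in seq_len(n)) for (p in 1:3) { # SP, SS, DP rows
    j_lin <- c(j_lin, (i - 1) * 4 + p)
    j_tidx <- c(j_tidx, ti(sprintf("J.%s.%s", region[i], pops[p])))
  }

  amp <- arch$C * base$exo$amplitude
  onset <- rep(base$exo$onset, n)
  if (any(arch$latent > 0)) {
    amp <- amp + arch$latent * base$exo$latent_amplitude
    onset[arch$latent > 0] <- base$exo$latent_onset
  }

  list(n = n,
       K = vapply(seq_len(n), function(i) base$node$K, numeric(4)),
       Gbase = Gbase, g_lin = g_lin, g_tidx = g_tidx, g_sp = g_sp,
       coupling = cp,
       Jbase = Jbase, j_lin = j_lin, j_tidx = j_tidx,
       Lbase = unname(base$obs$L), l_tidx = ti(sprintf("L.%s", nodes)),
       exo_amp = unname(amp), exo_onset = onset,
       exo_width = rep(base$exo$width, n),
       b_ext = ti("B.extrinsic"), b_self = ti("B.self"),
       r = base$node$r, v0 = base$node$v0)
}

# allocation-light prediction used by the inversion inner loop
.fast_predict_one <- function(priors, tv, deviant, tspan, dt, record_every) {
  f <- priors$fast
  bext <- if (deviant && !is.na(f$b_ext)) tv[f$b_ext] else 0
  bself <- if (deviant && !is.na(f$b_self)) tv[f$b_self] else 0

  Gc <- f$Gbase
  Gc[f$g_lin] <- Gc[f$g_lin] * exp(tv[f$g_tidx] + bself * f$g_sp)
  mk <- function(cl) {
    M <- cl$Mb
    if (length(cl$lin))
      M[cl$lin] <- M[cl$lin] * exp(tv[cl$tidx] + bext * cl$bflag)
    M
  }
  J <- f$Jbase
  J[f$j_lin] <- J[f$j_lin] * exp(tv[f$j_tidx])
  L <- f$Lbase * exp(tv[f$l_tidx])

  simulate_cmc_cpp(f$K, Gc, mk(f$coupling$fwd), mk(f$coupling$bwd),
                   mk(f$coupling$lat), f$exo_amp, f$exo_onset, f$exo_width,
                   J, L, f$r, f$v0, tspan[1], tspan[2], dt, record_every,
                   FALSE)
}

#' Zero (prior-mean) parameter vector for a prior specification
#' @param priors A [cmc_priors()] object.
#' @return Named numeric vector of zeros, one entry per parameter.
#' @export
theta_init <- function(priors) {
  setNames(rep(0, nrow(priors$table)), priors$table$name)
}

# realize condition-specific simulator inputs from a parameter vector
theta_to_sim <- function(priors, theta, condition = c("standard", "deviant")) {
  condition <- match.arg(condition)
  arch <- priors$arch
  nodes <- arch$nodes
  region <- priors$region
  n <- length(nodes)
  base <- priors$base
  th <- function(nm) if (nm %in% names(theta)) theta[[nm]] else 0
  deviant <- condition == "deviant"

  coupling <- list()
  for (cls in c("fwd", "bwd", "lat")) {
    A <- arch[[paste0("A_", cls)]]
    Bm <- arch[[paste0("B_", cls)]]
    M <- A * base$gains[[cls]]
    idx <- which(A != 0, arr.ind = TRUE)
    if (nrow(idx)) {
      for (k in seq_len(nrow(idx))) {
        i <- idx[k, "row"]; j <- idx[k, "col"]
        nm <- sprintf("A.%s.%s>%s", cls, nodes[j], nodes[i])
        s <- th(nm)
        if (deviant && Bm[i, j] != 0) s <- s + th("B.extrinsic")
        M[i, j] <- M[i, j] * exp(s)
      }
    }
    coupling[[cls]] <- M
  }

  params <- vector("list", n)
  for (i in seq_len(n)) {
    p <- base$node
    for (pop in cmc_populations()) {
      s <- th(sprintf("G.%s.%s", region[i], pop))
      if (deviant && arch$B_self[[i]] && pop == "SP") s <- s + th("B.self")
      p$G[pop, pop] <- p$G[pop, pop] * exp(s)
    }
    params[[i]] <- p
  }

  J <- base$obs$J
  colnames(J) <- nodes
  for (i in seq_len(n))
    for (pop in c("SP", "SS", "DP"))
      J[pop, i] <- J[pop, i] * exp(th(sprintf("J.%s.%s", region[i], pop)))
  L <- base$obs$L
  for (i in seq_len(n)) L[i] <- L[i] * exp(th(sprintf("L.%s", nodes[i])))
  obs <- observation_params(L = unname(L), J = J, noise_sd = 0, nodes = nodes)

  list(coupling = coupling, params = params, obs = obs, exo = base$exo)
}

#' Predict the two-condition evoked response for a parameter vector
#'
#' Runs the generative model under the standard and deviant conditions
#' (deviant-specific gain modulations applied to the masked connections) and
#' returns the noiseless per-node virtual-electrode signals.
#'
#' @param priors A [cmc_priors()] object.
#' @param theta Named log-scaling parameter vector (missing names = 0).
#' @param tspan,dt,fs Integration window (ms), step (ms), output rate (Hz).
#' @param conditions Conditions to simulate.
#' @return List with per-condition signal matrices (`nodes x time`), the
#'   sample times, and the stacked prediction vector `yhat` used by the
#'   inversion.
#' @export
predict_response <- function(priors, theta = theta_init(priors),
                             tspan = c(-100, 300), dt = 1, fs = 500,
                             conditions = c("standard", "deviant")) {
  period <- 1000 / fs
  record_every <- period / dt
  if (abs(record_every - round(record_every)) > 1e-9)
    stop("integration step dt must divide the output sample period 1000/fs")
  record_every <- as.integer(round(record_every))

  nm <- priors$table$name
  tv <- numeric(length(nm))
  if (length(theta)) {
    hit <- match(names(theta), nm)
    if (anyNA(hit)) stop("unknown parameter names in theta: ",
                         paste(names(theta)[is.na(hit)], collapse = ", "))
    tv[hit] <- theta
  }

  out <- list()
  for (cond in conditions) {
    res <- .fast_predict_one(priors, tv, cond == "deviant", tspan, dt,
                             record_every)
    if (!is.na(res$diverged_at))
      stop(sprintf("numerically unstable parameter set: states diverged at t = %.1f ms",
                   res$diverged_at))
    rownames(res$y) <- priors$nodes
    out[[cond]] <- res$y
    out$time <- drop(res$time)
  }
  out$yhat <- as.numeric(unlist(lapply(conditions, function(cn) out[[cn]])))
  out$conditions <- conditions
  out
}
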