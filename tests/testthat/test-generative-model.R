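test_that("centred sigmoid is zero at threshold, bounded, and matches the closed form", {
  p <- cmc_node_params()
  expect_identical(sigmoid_firing(p$v0, p), 0)
  expect_lt(abs(sigmoid_firing(1e6, p) - 0.5), 1e-12)      # upper saturation
  expect_lt(abs(sigmoid_firing(-1e6, p) + 0.5), 1e-12)     # lower saturation
  # hand-evaluated logistic at v0 + 1/r: 1/(1+e^-1) - 1/2
  expect_equal(sigmoid_firing(p$v0 + 1 / p$r, p),
               1 / (1 + exp(-1)) - 0.5, tolerance = 1e-12)
  # monotone non-decreasing
  v <- seq(-20, 20, by = 0.5)
  expect_true(all(diff(sigmoid_firing(v, p)) >= 0))
  expect_error(sigmoid_firing(NaN, p), "non-finite")
})

test_that("node derivative follows the printed second-order equations", {
  p <- cmc_node_params()
  s0 <- population_state()
  d0 <- node_derivative(s0, 0, 0, p)
  expect_identical(unname(d0$x_v), rep(0, 4))   # origin is a fixed point
  expect_identical(unname(d0$x_i), rep(0, 4))

  # exogenous drive e on SS moves only the SS current: d(x_i,SS)/dt = K_SS e
  e <- 0.7
  dS <- node_derivative(s0, 0, c(0, e, 0, 0), p)
  expect_equal(unname(dS$x_i), c(0, p$K[["SS"]] * e, 0, 0))
  expect_identical(unname(dS$x_v), rep(0, 4))

  # random small state matches an independently coded scalar evaluation
  set.seed(42)
  for (rep in 1:5) {
    xv <- rnorm(4, 0, 0.3); xi <- rnorm(4, 0, 0.3)
    aff <- rnorm(4, 0, 0.2); exo <- rnorm(4, 0, 0.2)
    got <- node_derivative(population_state(xv, xi), aff, exo, p)
    d <- 1 / (1 + exp(-p$r * (xv - p$v0))) - 0.5
    U <- aff + as.numeric(p$G %*% d) + exo
    expect_equal(unname(got$x_v), xi)
    expect_equal(unname(got$x_i), p$K * U - 2 * p$K * xi - p$K^2 * xv,
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  expect_error(node_derivative(s0, afferent = c(1, 2), params = p),
               "per population")
})

test_that("network derivative routes extrinsic drive by the laminar rules", {
  arch <- two_node_arch()
  p <- cmc_node_params()
  # decoupled limit: zero coupling equals independent node derivatives
  zero_cp <- list(fwd = matrix(0, 2, 2), bwd = matrix(0, 2, 2),
                  lat = matrix(0, 2, 2))
  sts <- list(population_state(c(0.4, -0.2, 0.1, 0.3), rnorm(4)),
              population_state(rnorm(4), rnorm(4)))
  net <- network_derivative(sts, arch, p, zero_cp, exo = 0, t = 0)
  for (i in 1:2) {
    ind <- node_derivative(sts[[i]], 0, 0, p)
    expect_equal(net[[i]]$x_i, ind$x_i)
  }

  # single forward edge lA1 -> lSTG: source SP firing drives target SS and
  # DP currents; target SP and II receive nothing
  g <- 6
  cp <- list(fwd = matrix(c(0, g, 0, 0), 2, 2), bwd = matrix(0, 2, 2),
             lat = matrix(0, 2, 2))
  src <- population_state(c(1, 0, 0, 0), numeric(4))  # depolarised SP
  tgt <- population_state()
  net <- network_derivative(list(src, tgt), arch, p, cp, exo = 0, t = 0)
  f <- sigmoid_firing(1, p)
  expect_equal(net[[2]]$x_i[["SS"]], p$K[["SS"]] * g * f)
  expect_equal(net[[2]]$x_i[["DP"]], p$K[["DP"]] * g * f)
  expect_identical(net[[2]]$x_i[["SP"]], 0)
  expect_identical(net[[2]]$x_i[["II"]], 0)

  # full two-node system agrees with the independently coded oracle RHS
  op <- oracle_params_from(arch)
  x <- rnorm(16, 0, 0.3)
  sts <- lapply(1:2, function(i)
    population_state(x[(i - 1) * 4 + 1:4], x[8 + (i - 1) * 4 + 1:4]))
  net <- network_derivative(sts, arch, p, default_coupling(arch),
                            exo = exogenous_input(), t = 50)
  # oracle packs voltages (4 x n) then currents (4 x n)
  ora <- oracle_rhs(50, x, op)[[1]]
  expect_equal(unlist(lapply(net, function(s) unname(s$x_v))),
               ora[1:8], tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unlist(lapply(net, function(s) unname(s$x_i))),
               ora[9:16], tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("simulated ERP stays at the fixed point without input and is causal", {
  arch <- test_space()$models[[14]]
  res0 <- simulate_erp(arch, exo = exogenous_input(amplitude = 0,
                                                   latent_amplitude = 0))
  expect_identical(max(abs(res0$y)), 0)

  res <- simulate_erp(arch)
  peak_t <- res$time[which.max(abs(colMeans(res$y)))]
  expect_gt(peak_t, 0)          # response follows, not precedes, the input
  expect_equal(ncol(res$y), 201) # 500 Hz over -100..300 ms
})

test_that("step-halving changes the integrated response negligibly", {
  arch <- test_space()$models[[14]]
  y1 <- simulate_erp(arch, dt = 1)$y
  y05 <- simulate_erp(arch, dt = 0.5)$y
  y025 <- simulate_erp(arch, dt = 0.25)$y
  # 4th-order scheme: halving the step shrinks the difference ~16-fold
  expect_lt(max(abs(y1 - y05)), 1e-4)
  expect_lt(max(abs(y05 - y025)), max(abs(y1 - y05)) / 8)
})

test_that("two-node simulation matches the brute-force adaptive-solver oracle", {
  skip_if_not_installed("deSolve")
  arch <- two_node_arch()
  res <- simulate_erp(arch, dt = 0.5)
  op <- oracle_params_from(arch)
  obs <- observation_params(nodes = arch$nodes)
  ora <- oracle_simulate(op, obs$J, unname(obs$L))
  scale <- max(abs(ora$y))
  expect_gt(scale, 0.01)  # the fixture actually produces a response
  expect_lt(max(abs(res$y - ora$y)) / scale, 1e-4)
})

test_that("single-node simulation matches the oracle", {
  skip_if_not_installed("deSolve")
  arch <- one_node_arch()
  res <- simulate_erp(arch, obs = observation_params(nodes = arch$nodes),
                      dt = 0.5)
  op <- oracle_params_from(arch)
  obs <- observation_params(nodes = arch$nodes)
  ora <- oracle_simulate(op, obs$J, unname(obs$L))
  expect_lt(max(abs(res$y - ora$y)) / max(abs(ora$y)), 1e-4)
})

test_that("divergent parameter sets are signalled with the divergence time", {
  arch <- two_node_arch()
  bad <- default_coupling(arch)
  bad$fwd[2, 1] <- Inf
  expect_error(simulate_erp(arch, coupling = bad), "diverged at")
})

test_that("observation projection is the L-scaled J-weighted voltage sum", {
  obs <- observation_params()
  # unit voltages with default priors: 0.8 + 0.2 + 0.2 = 1.2 per node
  states <- matrix(1, 4, 6)
  expect_equal(unname(project_observation(states, obs)), rep(1.2, 6))
  # J = 0 kills the signal
  obs0 <- observation_params(J = matrix(0, 4, 6))
  expect_identical(unname(project_observation(states, obs0)), rep(0, 6))
  # homogeneity in the states and in L
  set.seed(7)
  st <- matrix(rnorm(24), 4, 6)
  expect_equal(project_observation(3 * st, obs),
               3 * project_observation(st, obs))
  obs2 <- observation_params(L = rep(2, 6))
  expect_equal(project_observation(st, obs2), 2 * project_observation(st, obs))
  expect_error(observation_params(L = c(-1, rep(1, 5))), "non-negative")
})

test_that("default priors carry the documented laminar contribution weights", {
  pri <- default_priors()
  J <- pri$obs$J
  expect_equal(unname(J["SP", ]), rep(0.8, 6))
  expect_equal(unname(J["SS", ]), rep(0.2, 6))
  expect_equal(unname(J["DP", ]), rep(0.2, 6))
  expect_equal(unname(J["II", ]), rep(0, 6))       # only 3 nonzero weights
  expect_equal(colSums(J != 0), setNames(rep(3, 6), cmc_nodes()))
  # homologous nodes share identical contribution vectors
  for (pair in cmc_node_pairs())
    expect_identical(J[, pair[1]], J[, pair[2]], ignore_attr = TRUE)
  expect_true(all(pri$node$K > 0))
  expect_true(all(diag(pri$node$G) < 0))           # inhibitory self-gain
})

test_that("hemisphere symmetry of J survives arbitrary parameter vectors", {
  arch <- test_space()$models[[14]]
  pr <- cmc_priors(arch)
  set.seed(11)
  th <- theta_init(pr)
  th[] <- rnorm(length(th), 0, 0.3)
  sim <- microdcm:::theta_to_sim(pr, th, "deviant")
  J <- sim$obs$J
  for (pair in cmc_node_pairs())
    expect_identical(J[, pair[1]], J[, pair[2]], ignore_attr = TRUE)
})

test_that("the fixed point is linearly stable at default priors", {
  arch <- test_space()$models[[14]]
  f <- function(x) {
    sts <- lapply(1:6, function(i)
      population_state(x[(i - 1) * 8 + 1:4], x[(i - 1) * 8 + 5:8]))
    d <- network_derivative(sts, arch, coupling = default_coupling(arch),
                            exo = 0, t = 0)
    unlist(lapply(d, function(s) c(s$x_v, s$x_i)))
  }
  x0 <- rep(0, 48); h <- 1e-6
  Jm <- vapply(1:48, function(j) {
    xp <- x0; xp[j] <- h; xm <- x0; xm[j] <- -h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(48))
  expect_lt(max(Re(eigen(Jm, only.values = TRUE)$values)), 0)
})
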