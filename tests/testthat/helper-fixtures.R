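# Shared fixtures: small architectures, quick inversion settings, and a
# cached model space (building it is cheap but used everywhere).

test_space <- local({
  space <- NULL
  function() {
    if (is.null(space)) space <<- build_model_space()
    space
  }
})

# two-node hierarchy: input node lA1 feeding lSTG
two_node_arch <- function() {
  nodes <- c("lA1", "lSTG")
  A_fwd <- matrix(c(0, 1, 0, 0), 2, 2)  # lA1 -> lSTG (row = target)
  A_bwd <- t(A_fwd)
  network_architecture(nodes = nodes, A_fwd = A_fwd, A_bwd = A_bwd,
                       C = c(1, 0), B_fwd = A_fwd,
                       model_id = 99L, mod_classes = "F")
}

one_node_arch <- function() {
  nodes <- "lA1"
  z <- matrix(0, 1, 1)
  network_architecture(nodes = nodes, A_fwd = z, A_bwd = z, C = 1,
                       model_id = 98L)
}

# fast settings for smoke fits
quick_settings <- function(max_iter = 12, dt = 2)
  inversion_settings(max_iter = max_iter, dt = dt)

# simulate one subject from model-14 priors with the given parameter values
simulate_subject14 <- function(theta = c(B.extrinsic = 0.4, B.self = 0.4),
                               noise_sd = 0.02, seed = 1, dt = 1) {
  arch <- test_space()$models[[14]]
  pr <- cmc_priors(arch)
  r <- predict_response(pr, theta, dt = dt)
  ds <- evoked_dataset(r$standard, r$deviant, r$time)
  add_observation_noise(ds, noise_sd, seed = seed)
}
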