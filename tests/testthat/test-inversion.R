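test_that("free energy reduces to accuracy when posterior equals prior", {
  set.seed(1)
  X <- cbind(rnorm(30))
  theta_true <- 0.5
  y <- drop(X * theta_true) + rnorm(30, 0, 0.1)
  mu <- c(a = 0)
  F <- free_energy(y, rep(0, 30), X, mu, prior_mean = c(a = 0),
                   prior_var = c(a = 1), lambda = log(100),
                   lambda_prior = c(0, 0), Sigma = matrix(1, 1, 1))
  expect_equal(attr(F, "complexity_theta"), 0, tolerance = 1e-12)
  expect_equal(attr(F, "complexity_lambda"), 0)
  expect_equal(as.numeric(F), attr(F, "accuracy"))
})

test_that("free energy at the analytic posterior equals the closed-form log evidence", {
  # 1-parameter linear-Gaussian model with known noise precision: the
  # Laplace bound is tight, so F must equal log p(y) to numerical precision
  set.seed(2)
  n <- 25
  X <- cbind(rnorm(n))
  s0sq <- 0.8                      # prior variance of theta
  pe <- 50                         # known noise precision
  y <- drop(X) * 0.4 + rnorm(n, 0, sqrt(1 / pe))

  Sp <- solve(pe * crossprod(X) + 1 / s0sq)
  mup <- drop(Sp %*% (pe * crossprod(X, y)))
  F <- free_energy(y, drop(X) * mup, X, c(a = mup),
                   prior_mean = c(a = 0), prior_var = c(a = s0sq),
                   lambda = log(pe), lambda_prior = c(0, 0))
  # closed form: y ~ N(0, s0sq X X' + I/pe)
  Cov <- s0sq * tcrossprod(X) + diag(n) / pe
  logZ <- -0.5 * (n * log(2 * pi) + determinant(Cov)$modulus +
                    drop(y %*% solve(Cov, y)))
  expect_equal(as.numeric(F), as.numeric(logZ), tolerance = 1e-6)
})

test_that("an unused parameter with nonzero prior variance never increases F", {
  set.seed(3)
  n <- 20
  X <- cbind(rnorm(n))
  y <- drop(X) * 0.3 + rnorm(n, 0, 0.2)
  pe <- 25
  Sp <- solve(pe * crossprod(X) + 1)
  mup <- drop(Sp %*% (pe * crossprod(X, y)))
  F1 <- free_energy(y, drop(X) * mup, X, c(a = mup),
                    prior_mean = c(a = 0), prior_var = c(a = 1),
                    lambda = log(pe), lambda_prior = c(0, 0))
  X2 <- cbind(X, 0)                # second parameter never enters the fit
  F2 <- free_energy(y, drop(X) * mup, X2, c(a = mup, b = 0),
                    prior_mean = c(a = 0, b = 0), prior_var = c(a = 1, b = 1),
                    lambda = log(pe), lambda_prior = c(0, 0))
  expect_lte(as.numeric(F2), as.numeric(F1) + 1e-8)
})

test_that("a singular posterior precision is signalled, not regularized away", {
  y <- rnorm(5)
  X <- matrix(0, 5, 2)             # completely unidentified pair
  expect_error(
    free_energy(y, rep(0, 5), X, c(a = 0, b = 0),
                prior_mean = c(a = 0, b = 0),
                prior_var = c(a = Inf, b = Inf), lambda = 0),
    "singular|infinite")
})

test_that("noiseless data from the prior-mean model yields a posterior near zero", {
  arch <- test_space()$models[[14]]
  pr <- cmc_priors(arch, free = c("A", "B"))
  r <- predict_response(pr, dt = 2)
  ds <- evoked_dataset(r$standard, r$deviant, r$time)
  fit <- invert(ds, arch, pr, settings = quick_settings())
  expect_lt(max(abs(fit$theta[fit$free])), 0.02)
  expect_true(all(diff(fit$F_trace) >= 0))
})

test_that("a planted extrinsic gain is recovered within posterior uncertainty", {
  arch <- test_space()$models[[14]]
  pr <- cmc_priors(arch, free = c("A", "B"))
  target <- "A.fwd.lA1>lSTG"
  th <- setNames(c(0.5, 0.4, 0.4), c(target, "B.extrinsic", "B.self"))
  r <- predict_response(pr, th, dt = 2)
  ds <- add_observation_noise(
    evoked_dataset(r$standard, r$deviant, r$time), 0.02, seed = 5)
  fit <- invert(ds, arch, pr, settings = quick_settings(max_iter = 24))
  est <- fit$theta[[target]]
  sd_est <- sqrt(fit$Sigma[target, target])
  expect_gt(est, 0)
  expect_lt(abs(est - 0.5), 2 * sd_est + 0.1)
  # posterior covariance is symmetric positive definite
  expect_equal(fit$Sigma, t(fit$Sigma), tolerance = 1e-10)
  expect_gt(min(eigen(fit$Sigma, symmetric = TRUE)$values), 0)
})

test_that("zero-variance parameters are bit-identical before and after inversion", {
  arch <- test_space()$models[[14]]
  pr <- cmc_priors(arch, free = c("A", "B"))
  r <- predict_response(pr, c(B.extrinsic = 0.3), dt = 2)
  ds <- add_observation_noise(
    evoked_dataset(r$standard, r$deviant, r$time), 0.05, seed = 6)
  start <- theta_init(pr)
  start["J.STG.DP"] <- 0.123456789  # fixed block, non-default start
  fit <- invert(ds, arch, pr, settings = quick_settings(max_iter = 6),
                theta_start = start)
  fixed <- setdiff(names(fit$theta), fit$free)
  expect_identical(fit$theta[["J.STG.DP"]], 0.123456789)
  expect_identical(unname(fit$theta[setdiff(fixed, "J.STG.DP")]),
                   rep(0, length(fixed) - 1))
})

test_that("the generating architecture beats a wrong-family one on free energy", {
  space <- test_space()
  gen <- space$models[[14]]
  alt <- space$models[[9]]         # interhemispheric family, no latent input
  pr_gen <- cmc_priors(gen, free = c("A", "B"))
  wins <- 0
  for (s in 1:3) {
    th <- c(B.extrinsic = 0.4, B.self = 0.4)
    r <- predict_response(pr_gen, th, dt = 2)
    ds <- add_observation_noise(
      evoked_dataset(r$standard, r$deviant, r$time), 0.03, seed = 100 + s)
    f_gen <- invert(ds, gen, pr_gen, settings = quick_settings())$F
    f_alt <- invert(ds, alt, cmc_priors(alt, free = c("A", "B")),
                    settings = quick_settings())$F
    if (f_gen > f_alt) wins <- wins + 1
  }
  expect_gte(wins, 2)
})

test_that("posterior summaries are labelled, ordered, and round-trip CSV bit-exactly", {
  arch <- test_space()$models[[14]]
  pr <- cmc_priors(arch, free = c("A", "B"))
  r <- predict_response(pr, c(B.extrinsic = 0.3), dt = 2)
  ds <- add_observation_noise(
    evoked_dataset(r$standard, r$deviant, r$time), 0.05, seed = 8)
  fit <- invert(ds, arch, pr, settings = quick_settings(max_iter = 4))

  sj <- posterior_summary(fit, "J")
  # hemisphere-tied: 3 region pairs x 3 contributing populations
  expect_equal(nrow(sj), 9)
  expect_setequal(sj$parameter,
                  as.vector(outer(c("A1", "STG", "IFG"), c("SP", "SS", "DP"),
                                  function(a, b) sprintf("J.%s.%s", a, b))))
  expect_equal(sj$mean, rep(0, 9))  # J fixed in this fit

  sv <- posterior_summary(fit, "V")
  expect_true(all(sv$block %in% c("A", "B")))
  expect_identical(sv$parameter,
                   pr$table$name[pr$table$block %in% c("A", "B")])

  path <- withr::local_tempfile(fileext = ".csv")
  write_parameter_csv(sv, path)
  back <- read_parameter_csv(path, template = sv)
  expect_identical(back$mean, sv$mean)
  expect_identical(back$sd, sv$sd)
  expect_identical(back$parameter, sv$parameter)

  expect_error(posterior_summary(fit, "Q"), "arg")
})

test_that("two-pass inversion fixes pass-1 observation parameters in pass 2", {
  arch <- test_space()$models[[14]]
  pr <- cmc_priors(arch)
  th <- c(B.extrinsic = 0.4, B.self = 0.4, J.STG.DP = -0.3)
  r <- predict_response(pr, th, dt = 2)
  ds <- add_observation_noise(
    evoked_dataset(r$standard, r$deviant, r$time), 0.02, seed = 9)
  both <- invert_two_pass(ds, arch, settings = quick_settings(max_iter = 8))
  jnames <- grep("^J\\.", names(both$pass1$theta), value = TRUE)
  expect_identical(both$pass2$theta[jnames], both$pass1$theta[jnames])
  expect_true(all(grepl("^(A\\.|B\\.|G\\.)", both$pass2$free)))
})
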