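#' Variational-Laplace free energy
#'
#' Computes the Laplace approximation to the negative variational free
#' energy, \eqn{F = \langle \log p(y|\theta) \rangle_q - KL(q\|p)}, for a
#' Gaussian posterior `q` over log-scaling parameters and an i.i.d. Gaussian
#' noise model with log-precision `lambda`. `F` is a lower bound on the log
#' model evidence and decomposes into an accuracy term and complexity
#' penalties for the parameters and the noise hyperparameter.
#'
#' Parameters with zero prior variance are treated as fixed and excluded
#' from the free subspace (they contribute nothing to the KL term).
#'
#' @param y Data vector.
#' @param pred Model prediction at the posterior mean.
#' @param jac Jacobian of the prediction with respect to the free
#'   parameters (N x k), evaluated at the posterior mean.
#' @param mu Posterior mean over all parameters (named).
#' @param prior_mean,prior_var Prior mean and variance per parameter (same
#'   names/order as `mu`). Zero variance marks a fixed parameter.
#' @param lambda Posterior (point) estimate of the noise log-precision.
#' @param lambda_prior `c(mean, variance)` of the Gaussian hyperprior on
#'   `lambda`; variance 0 treats the noise precision as known (no
#'   hyperparameter complexity).
#' @param Sigma Optional posterior covariance over the free parameters; if
#'   omitted it is the Gauss-Newton posterior
#'   \eqn{(e^\lambda J'J + \Pi_0)^{-1}}.
#' @param lambda_var Optional posterior variance of `lambda` (defaults to
#'   its Newton curvature).
#' @return Numeric `F` (nats) with attributes `accuracy`,
#'   `complexity_theta`, `complexity_lambda`, and `Sigma`.
#' @export
free_energy <- function(y, pred, jac, mu, prior_mean, prior_var,
                        lambda, lambda_prior = c(0, 0),
                        Sigma = NULL, lambda_var = NULL) {
  r <- y - pred
  N <- length(y)
  free <- which(prior_var > 0)
  k <- length(free)
  pe <- exp(lambda)

  if (k > 0) {
    if (is.null(jac)) stop("jacobian required when free parameters exist")
    JtJ <- crossprod(jac)
    Pi0 <- diag(1 / prior_var[free], k)
    if (is.null(Sigma)) {
      P <- pe * JtJ + Pi0
      Sigma <- tryCatch(solve(P), error = function(e)
        stop("singular posterior precision: ", conditionMessage(e)))
    }
    eS <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
    if (any(eS <= 0))
      stop("singular or indefinite posterior covariance in free_energy")
    tr_pred <- sum(JtJ * Sigma)           # tr(J'J Sigma)
    dm <- mu[free] - prior_mean[free]
    kl_theta <- 0.5 * (sum(diag(Pi0 %*% Sigma)) + sum(dm * (1 / prior_var[free]) * dm) -
                         k + sum(log(prior_var[free])) - sum(log(eS)))
  } else {
    tr_pred <- 0
    kl_theta <- 0
    Sigma <- matrix(0, 0, 0)
  }

  accuracy <- -0.5 * pe * (sum(r^2) + tr_pred) +
    0.5 * N * (lambda - log(2 * pi))

  kl_lambda <- 0
  if (lambda_prior[2] > 0) {
    if (is.null(lambda_var))
      lambda_var <- 1 / (0.5 * pe * (sum(r^2) + tr_pred) + 1 / lambda_prior[2])
    kl_lambda <- 0.5 * (lambda_var / lambda_prior[2] +
                          (lambda - lambda_prior[1])^2 / lambda_prior[2] -
                          1 + log(lambda_prior[2] / lambda_var))
  }

  F <- accuracy - kl_theta - kl_lambda
  attr(F, "accuracy") <- accuracy
  attr(F, "complexity_theta") <- kl_theta
  attr(F, "complexity_lambda") <- kl_lambda
  attr(F, "Sigma") <- Sigma
  F
}

#' Inversion settings
#'
#' @param max_iter Maximum Gauss-Newton iterations.
#' @param tol Convergence tolerance: the fit stops when F improves by less
#'   than `tol` nats over two consecutive accepted iterations.
#' @param dt Integration step (ms).
#' @param fs Output sampling rate (Hz); must match the data.
#' @param h Finite-difference step for the response Jacobian.
#' @param lambda_prior `c(mean, variance)` hyperprior on the noise
#'   log-precision.
#' @param max_reject Trust-region halvings per iteration before giving up.
#' @return List of settings.
#' @export
inversion_settings <- function(max_iter = 64, tol = 0.01, dt = 1, fs = 500,
                               h = 1e-3, lambda_prior = c(0, 16),
                               max_reject = 6) {
  list(max_iter = max_iter, tol = tol, dt = dt, fs = fs, h = h,
       lambda_prior = lambda_prior, max_reject = max_reject)
}

# central-difference Jacobian of the stacked response w.r.t. free parameters
.response_jacobian <- function(priors, theta, free_names, tspan, dt, fs, h) {
  cols <- lapply(free_names, function(nm) {
    tp <- theta; tm <- theta
    tp[nm] <- tp[nm] + h
    tm[nm] <- tm[nm] - h
    (predict_response(priors, tp, tspan, dt, fs)$yhat -
       predict_response(priors, tm, tspan, dt, fs)$yhat) / (2 * h)
  })
  do.call(cbind, cols)
}

# Newton updates of the noise log-precision given current residuals
.update_lambda <- function(lambda, rss_eff, N, lp) {
  rss_eff <- max(rss_eff, 1e-12)  # guard: exactly noiseless data
  if (!is.finite(lambda)) lambda <- log(N / rss_eff)
  for (i in 1:8) {
    pe <- exp(lambda)
    g <- 0.5 * N - 0.5 * pe * rss_eff -
      if (lp[2] > 0) (lambda - lp[1]) / lp[2] else 0
    Hn <- -0.5 * pe * rss_eff - if (lp[2] > 0) 1 / lp[2] else 0
    step <- g / Hn
    lambda <- lambda - max(min(step, 4), -4)
    if (abs(step) < 1e-6) break
  }
  lambda
}

#' Invert a generative model for one subject
#'
#' Variational-Laplace estimation of the posterior over log-scaling
#' parameters from a two-condition evoked dataset. A
#' Levenberg-Marquardt-regularised Gauss-Newton ascent maximises the free
#' energy; steps that do not increase F shrink the trust region and are
#' discarded, so the recorded F trace is non-decreasing. The noise
#' log-precision hyperparameter is updated by Newton steps inside the same
#' loop. Both conditions are fitted jointly; deviant-specific gain
#' modulations apply to the connections flagged by the architecture's
#' modulation masks.
#'
#' @param data An `evoked_dataset` with `standard` and `deviant` conditions.
#' @param arch A [network_architecture()].
#' @param priors A [cmc_priors()] object (defaults to free A, B, J, L
#'   blocks).
#' @param settings See [inversion_settings()].
#' @param theta_start Starting parameter vector; fixed (zero-variance)
#'   parameters keep their starting values exactly.
#' @return Object of class `inversion_result`: posterior means (`theta`,
#'   full vector), free-parameter covariance (`Sigma`), free energy `F` and
#'   its iteration trace, predicted responses, residuals, the noise
#'   log-precision, and a convergence flag.
#' @export
invert <- function(data, arch, priors = cmc_priors(arch),
                   settings = inversion_settings(),
                   theta_start = NULL) {
  stopifnot(inherits(data, "evoked_dataset"))
  if (is.null(data$data$standard) || is.null(data$data$deviant))
    stop("both standard and deviant conditions are required")
  tspan <- range(data$time)
  fs <- data$fs
  dt <- settings$dt
  y <- c(as.numeric(data$data$standard), as.numeric(data$data$deviant))
  N <- length(y)

  tab <- priors$table
  theta <- theta_init(priors)
  if (!is.null(theta_start)) theta[names(theta_start)] <- theta_start
  free <- tab$name[tab$var > 0]
  k <- length(free)
  pC <- setNames(tab$var, tab$name)
  p0 <- setNames(tab$mean, tab$name)
  p0[names(theta)[pC == 0]] <- theta[pC == 0]  # fixed entries anchored at start
  lp <- settings$lambda_prior

  pred <- predict_response(priors, theta, tspan, dt, fs)$yhat
  r <- y - pred
  lambda <- .update_lambda(log(N / sum(r^2)), sum(r^2), N, lp)

  Fcur <- -Inf
  F_trace <- numeric(0)
  nu <- 1 # LM damping
  converged <- FALSE
  it <- 0
  Sigma <- NULL
  jac <- NULL

  eval_F <- function(theta_c, jac_c, pred_c, lambda_c) {
    free_energy(y, pred_c, jac_c, theta_c, p0, pC,
                lambda_c, lambda_prior = lp)
  }

  while (it < settings$max_iter && k > 0) {
    it <- it + 1
    jac <- .response_jacobian(priors, theta, free, tspan, dt, fs, settings$h)
    pred <- predict_response(priors, theta, tspan, dt, fs)$yhat
    r <- y - pred
    JtJ <- crossprod(jac)
    Pi0 <- diag(1 / pC[free], k)
    pe <- exp(lambda)
    Sig0 <- solve(pe * JtJ + Pi0)
    lambda <- .update_lambda(lambda, sum(r^2) + sum(JtJ * Sig0), N, lp)
    pe <- exp(lambda)

    if (!is.finite(Fcur))
      Fcur <- as.numeric(eval_F(theta, jac, pred, lambda))

    grad <- pe * crossprod(jac, r) - (1 / pC[free]) * (theta[free] - p0[free])
    P <- pe * JtJ + Pi0

    accepted <- FALSE
    for (try in seq_len(settings$max_reject)) {
      step <- tryCatch(solve(P + nu * diag(diag(P), k), grad),
                       error = function(e) NULL)
      if (!is.null(step)) {
        cand <- theta
        cand[free] <- cand[free] + as.numeric(step)
        pred_c <- predict_response(priors, cand, tspan, dt, fs)$yhat
        Fc <- tryCatch(as.numeric(eval_F(cand, jac, pred_c, lambda)),
                       error = function(e) -Inf)
        if (is.finite(Fc) && Fc > Fcur) {
          theta <- cand
          pred <- pred_c
          dF <- Fc - Fcur
          Fcur <- Fc
          nu <- max(nu / 2, 1e-8)
          accepted <- TRUE
          break
        }
      }
      nu <- nu * 8
    }
    if (!accepted) {
      # no improving step within the trust-region budget: the ascent has
      # stalled at a (local) maximum
      converged <- length(F_trace) > 0
      break
    }
    F_trace <- c(F_trace, Fcur)
    nF <- length(F_trace)
    if (nF >= 3 && (F_trace[nF] - F_trace[nF - 2]) < settings$tol) {
      converged <- TRUE
      break
    }
  }

  # final posterior quantities at the accepted mean
  if (k > 0) {
    jac <- .response_jacobian(priors, theta, free, tspan, dt, fs, settings$h)
    pred <- predict_response(priors, theta, tspan, dt, fs)$yhat
    r <- y - pred
    Ff <- free_energy(y, pred, jac, theta, p0, pC, lambda, lambda_prior = lp)
    Sigma <- attr(Ff, "Sigma")
    dimnames(Sigma) <- list(free, free)
    Fcur <- as.numeric(Ff)
    if (length(F_trace) == 0) F_trace <- Fcur
  } else {
    pred <- predict_response(priors, theta, tspan, dt, fs)$yhat
    r <- y - pred
    Ff <- free_energy(y, pred, NULL, theta, p0, pC, lambda, lambda_prior = lp)
    Fcur <- as.numeric(Ff)
    F_trace <- Fcur
    Sigma <- matrix(0, 0, 0)
    converged <- TRUE
  }

  pr <- predict_response(priors, theta, tspan, dt, fs)
  structure(list(theta = theta, free = free, Sigma = Sigma,
                 F = Fcur, F_trace = F_trace, lambda = lambda,
                 predicted = pr[pr$conditions], residuals = r,
                 converged = converged, iterations = it,
                 priors = priors, model_id = arch$model_id),
            class = "inversion_result")
}

#' Two-pass inversion: observation parameters, then intrinsic coupling
#'
#' Pass 1 optimises the contribution weights `J` and electrode gains `L`
#' (with extrinsic coupling and condition effects) while the intrinsic
#' self-gains stay at their priors; pass 2 fixes the optimised `J`/`L` and
#' re-inverts to estimate the intrinsic self-gain scalings `G`.
#'
#' @inheritParams invert
#' @return List with elements `pass1` and `pass2` (both
#'   `inversion_result`).
#' @export
invert_two_pass <- function(data, arch, settings = inversion_settings()) {
  p1 <- invert(data, arch, cmc_priors(arch, free = c("A", "B", "J", "L")),
               settings)
  pr2 <- cmc_priors(arch, free = c("A", "B", "G"))
  start <- theta_init(pr2)
  keep <- grep("^(J|L)\\.", names(start), value = TRUE)
  start[keep] <- p1$theta[keep]
  p2 <- invert(data, arch, pr2, settings, theta_start = start)
  list(pass1 = p1, pass2 = p2)
}

#' Labelled posterior parameter table
#'
#' @param result An [invert()] result.
#' @param which `"V"` (extrinsic connection strengths and condition
#'   modulations), `"J"` (laminar contribution weights) or `"G_self"`
#'   (intrinsic self-gain scalings).
#' @return Data frame with one row per parameter: label, posterior mean and
#'   posterior SD (log-scaling units), in stable (prior-table) order.
#' @export
posterior_summary <- function(result, which = c("V", "J", "G_self")) {
  which <- match.arg(which)
  blocks <- switch(which, V = c("A", "B"), J = "J", G_self = "G")
  tab <- result$priors$table
  sel <- tab[tab$block %in% blocks, , drop = FALSE]
  sds <- setNames(rep(0, nrow(sel)), sel$name)
  fr <- intersect(sel$name, result$free)
  if (length(fr)) sds[fr] <- sqrt(diag(result$Sigma)[fr])
  data.frame(parameter = sel$name, block = sel$block,
             mean = unname(result$theta[sel$name]),
             sd = unname(sds), row.names = NULL)
}
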