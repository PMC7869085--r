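#' Evidence matrix constructor
#'
#' @param F Numeric subjects x models matrix of log model evidence (free
#'   energy, nats). Column names are model ids.
#' @param subjects Optional subject ids.
#' @param models Optional model ids (defaults to column names or 1..K).
#' @return Object of class `evidence_matrix`.
#' @export
evidence_matrix <- function(F, subjects = NULL, models = NULL) {
  F <- as.matrix(F)
  if (any(!is.finite(F))) stop("log evidences must be finite and complete")
  if (is.null(models)) models <- colnames(F)
  if (is.null(models)) models <- as.character(seq_len(ncol(F)))
  if (is.null(subjects)) subjects <- rownames(F)
  if (is.null(subjects)) subjects <- sprintf("S%03d", seq_len(nrow(F)))
  dimnames(F) <- list(subjects, models)
  structure(F, class = c("evidence_matrix", "matrix"))
}

.bms_result <- function(method, prob, ep = NULL, alpha = NULL,
                        families = NULL, family_prob = NULL,
                        family_ep = NULL, winner = NA, tie = FALSE,
                        seed = NA) {
  structure(list(method = method, prob = prob, ep = ep, alpha = alpha,
                 families = families, family_prob = family_prob,
                 family_ep = family_ep, winner = winner, tie = tie,
                 seed = seed),
            class = "bms_result")
}

.subset_ev <- function(ev, subset) {
  if (is.null(subset)) return(ev)
  subset <- as.character(subset)
  if (length(subset) == 0) stop("empty model subset")
  missing <- setdiff(subset, colnames(ev))
  if (length(missing))
    stop("unknown model ids in subset: ", paste(missing, collapse = ", "))
  ev[, subset, drop = FALSE]
}

#' Fixed-effects Bayesian model selection
#'
#' Posterior model probabilities are the softmax of the log evidences
#' summed over subjects, under a uniform (or supplied) model prior.
#'
#' @param ev An [evidence_matrix()].
#' @param subset Optional model ids to compare (default: all).
#' @param log_prior Optional log prior mass per model (recycled/normalised).
#' @return A `bms_result` with posterior probabilities and the winning id.
#' @export
ffx_compare <- function(ev, subset = NULL, log_prior = NULL) {
  ev <- .subset_ev(ev, subset)
  s <- colSums(ev)
  if (!is.null(log_prior)) s <- s + log_prior
  s <- s - max(s)
  prob <- exp(s) / sum(exp(s))
  top <- which(prob == max(prob))
  .bms_result("FFX", prob,
              winner = if (length(top) == 1) names(prob)[top] else NA,
              tie = length(top) > 1)
}

# variational Dirichlet update over model frequencies (random-effects BMS)
.rfx_alpha <- function(F, alpha0) {
  K <- ncol(F)
  alpha <- alpha0
  for (iter in 1:200) {
    lg <- sweep(F, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    lg <- lg - apply(lg, 1, max)
    g <- exp(lg)
    g <- g / rowSums(g)
    alpha_new <- alpha0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < 1e-8) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
  }
  alpha
}

# Dirichlet draws via normalised gammas
.rdirichlet <- function(n, alpha) {
  K <- length(alpha)
  x <- matrix(rgamma(n * K, shape = rep(alpha, each = n)), n, K)
  x / rowSums(x)
}

#' Random-effects Bayesian model selection
#'
#' Variational Dirichlet estimation of the population model frequencies
#' (prior alpha0 = 1 per model), with exceedance probabilities estimated by
#' Monte-Carlo sampling from the Dirichlet posterior.
#'
#' @param ev An [evidence_matrix()].
#' @param subset Optional model ids to compare.
#' @param n_samples Dirichlet draws for the exceedance probabilities.
#' @param seed Seed for the draws.
#' @param alpha0 Dirichlet prior counts (scalar or per model).
#' @return A `bms_result` with expected model probabilities (`prob`),
#'   exceedance probabilities (`ep`), the Dirichlet `alpha`, and winner by
#'   exceedance probability.
#' @export
rfx_compare <- function(ev, subset = NULL, n_samples = 1e5, seed = 1,
                        alpha0 = 1) {
  ev <- .subset_ev(ev, subset)
  if (ncol(ev) < 2) stop("random-effects BMS needs at least 2 models")
  K <- ncol(ev)
  alpha0 <- rep_len(alpha0, K)
  alpha <- .rfx_alpha(ev, alpha0)
  names(alpha) <- colnames(ev)
  prob <- alpha / sum(alpha)
  set.seed(seed)
  draws <- .rdirichlet(n_samples, alpha)
  wmax <- max.col(draws, ties.method = "first")
  ep <- tabulate(wmax, K) / n_samples
  names(ep) <- colnames(ev)
  top <- which(ep == max(ep))
  .bms_result("RFX", prob, ep = ep, alpha = alpha,
              winner = if (length(top) == 1) names(ep)[top] else NA,
              tie = length(top) > 1, seed = seed)
}

#' Family-wise Bayesian model comparison
#'
#' Compares families of models rather than individual models. Prior mass is
#' equalised across families regardless of family size (uniform within
#' family). For FFX the family probability is the summed posterior mass of
#' its members; for RFX the Dirichlet prior counts are rescaled per family
#' and family frequencies/exceedance probabilities are aggregates over
#' members.
#'
#' @param ev An [evidence_matrix()].
#' @param partition Named list of disjoint model-id vectors covering the
#'   compared set.
#' @param method `"FFX"` or `"RFX"`.
#' @param n_samples,seed Monte-Carlo settings for RFX exceedance
#'   probabilities.
#' @return A `bms_result` with per-model and per-family probabilities.
#' @export
family_compare <- function(ev, partition, method = c("FFX", "RFX"),
                           n_samples = 1e5, seed = 1) {
  method <- match.arg(method)
  ids <- unlist(partition)
  if (anyDuplicated(ids)) stop("families overlap: a model is in two families")
  partition <- lapply(partition, as.character)
  ids <- unlist(partition)
  nf <- length(partition)
  fam_of <- rep(names(partition), lengths(partition))
  names(fam_of) <- ids

  if (method == "FFX") {
    log_prior <- log(1 / (nf * lengths(partition)))[fam_of]
    res <- ffx_compare(ev, subset = ids, log_prior = unname(log_prior))
    fam_prob <- vapply(partition, function(m) sum(res$prob[m]), numeric(1))
    top <- which(fam_prob == max(fam_prob))
    .bms_result("FFX", res$prob, families = partition,
                family_prob = fam_prob,
                winner = if (length(top) == 1) names(fam_prob)[top] else NA,
                tie = length(top) > 1)
  } else {
    alpha0 <- (1 / lengths(partition))[fam_of]
    alpha0 <- alpha0 / sum(alpha0) * length(ids) # keep total prior count = K
    evs <- .subset_ev(ev, ids)
    alpha <- .rfx_alpha(evs, unname(alpha0))
    names(alpha) <- ids
    prob <- alpha / sum(alpha)
    set.seed(seed)
    draws <- .rdirichlet(n_samples, alpha)
    colnames(draws) <- ids
    fam_draws <- vapply(partition, function(m)
      rowSums(draws[, m, drop = FALSE]), numeric(n_samples))
    wmax <- max.col(fam_draws, ties.method = "first")
    fam_ep <- tabulate(wmax, nf) / n_samples
    names(fam_ep) <- names(partition)
    fam_prob <- vapply(partition, function(m) sum(prob[m]), numeric(1))
    top <- which(fam_ep == max(fam_ep))
    .bms_result("RFX", prob, alpha = alpha, families = partition,
                family_prob = fam_prob, family_ep = fam_ep,
                winner = if (length(top) == 1) names(fam_ep)[top] else NA,
                tie = length(top) > 1, seed = seed)
  }
}

#' Greedy (step-down) family search over the model space
#'
#' Applies the three family partitions in order: (1) with vs without left
#' IFG, (2) with vs without interhemispheric connections, (3) with vs
#' without the top-down latent input to right IFG. At each level both FFX
#' and RFX family comparisons are run on the surviving candidate set and
#' the winning family (by RFX exceedance probability, FFX reported
#' alongside) is carried forward. Candidate sets are intersected with the
#' models actually present in the evidence matrix, so the search also runs
#' on reduced model subspaces; a level where one side is empty is reported
#' as degenerate and skipped. Exact ties are reported as ties and stop the
#' descent.
#'
#' @param ev An [evidence_matrix()] (columns named by model id).
#' @param space A [build_model_space()] result.
#' @param n_samples,seed RFX Monte-Carlo settings.
#' @return Object of class `greedy_search`: per-level results and the
#'   surviving model id (model-level RFX winner within the final family if
#'   more than one survives).
#' @export
greedy_family_search <- function(ev, space, n_samples = 1e5, seed = 1) {
  candidates <- intersect(as.character(seq_along(space$models)), colnames(ev))
  steps <- list()
  tie <- FALSE
  for (lv in 1:3) {
    part <- lapply(family_partition(space, lv), as.character)
    part <- lapply(part, intersect, y = candidates)
    if (any(lengths(part) == 0)) {
      # one (or both) families unrepresented in the candidate set: the level
      # cannot discriminate, so the non-empty side (if any) survives
      nonempty <- names(part)[lengths(part) > 0]
      win <- if (length(nonempty) == 1) nonempty else NA
      steps[[names(space$family_tree)[lv]]] <-
        list(level = lv, degenerate = TRUE, winner = win,
             candidates = if (is.na(win)) candidates else part[[win]])
      if (!is.na(win)) candidates <- part[[win]]
      next
    }
    ffx <- family_compare(ev, part, "FFX")
    rfx <- family_compare(ev, part, "RFX", n_samples = n_samples,
                          seed = seed + lv)
    steps[[names(space$family_tree)[lv]]] <-
      list(level = lv, degenerate = FALSE, ffx = ffx, rfx = rfx,
           winner = rfx$winner, candidates = part)
    if (rfx$tie || is.na(rfx$winner)) {
      tie <- TRUE
      break
    }
    candidates <- part[[rfx$winner]]
  }
  survivor <- NA
  if (!tie) {
    if (length(candidates) == 1) {
      survivor <- candidates
    } else if (length(candidates) > 1) {
      final <- rfx_compare(ev, subset = candidates, n_samples = n_samples,
                           seed = seed + 7)
      survivor <- final$winner
      steps$final_model_level <- list(rfx = final)
    }
  }
  structure(list(steps = steps, survivor = survivor, tie = tie),
            class = "greedy_search")
}

#' Leave-one-out permutation Bayesian model selection
#'
#' Each permutation removes one uniformly drawn subject (with replacement
#' across permutations), reruns model-level BMS on the remainder, and
#' tallies the winning model.
#'
#' @param ev An [evidence_matrix()].
#' @param subset Optional model ids.
#' @param n_perm Number of permutations.
#' @param seed Seed for the held-out draws.
#' @param method `"rfx"` (winner by expected frequency) or `"ffx"`.
#' @return Data frame of winning-model frequencies (`model`, `wins`,
#'   `freq`), with the seed as an attribute.
#' @export
loo_bms_permutations <- function(ev, subset = NULL, n_perm = 1000, seed = 1,
                                 method = c("rfx", "ffx")) {
  method <- match.arg(method)
  ev <- .subset_ev(ev, subset)
  n <- nrow(ev)
  if (n < 2) stop("leave-one-out BMS needs at least 2 subjects")
  if (n_perm < 1) stop("n_perm must be at least 1")
  set.seed(seed)
  drop_idx <- sample.int(n, n_perm, replace = TRUE)
  winners <- character(n_perm)
  for (p in seq_len(n_perm)) {
    sub <- ev[-drop_idx[p], , drop = FALSE]
    winners[p] <- if (method == "ffx") {
      ffx_compare(evidence_matrix(sub))$winner
    } else {
      alpha <- .rfx_alpha(sub, rep(1, ncol(sub)))
      colnames(sub)[which.max(alpha)]
    }
  }
  tab <- sort(table(winners), decreasing = TRUE)
  out <- data.frame(model = names(tab), wins = as.integer(tab),
                    freq = as.numeric(tab) / n_perm, row.names = NULL)
  attr(out, "seed") <- seed
  attr(out, "n_perm") <- n_perm
  out
}
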