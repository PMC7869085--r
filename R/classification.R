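#' Assemble a feature table for classification
#'
#' Three feature sets mirror the study design: `V` (generative-model
#' effective connectivity strengths between nodes, plus condition
#' modulations), `J` (hemisphere-tied layer-by-node contribution weights)
#' and `ERF` (per-region mismatch difference-wave amplitudes).
#'
#' @param results For `V`/`J`: list of [invert()] results fitted with the
#'   same architecture. For `ERF`: list of [evoked_dataset()] objects.
#' @param kind `"V"`, `"J"` or `"ERF"`.
#' @param subjects,groups Subject ids and group labels (taken from the
#'   datasets for `ERF` when omitted).
#' @param window Mismatch window for `ERF` amplitudes.
#' @return Object of class `feature_table`: data frame with subject, group
#'   and named feature columns; the feature set is in attribute
#'   `feature_set`.
#' @export
assemble_features <- function(results, kind = c("V", "J", "ERF"),
                              subjects = NULL, groups = NULL,
                              window = c(80, 200)) {
  kind <- match.arg(kind)
  if (length(results) == 0) stop("empty result set")
  if (kind %in% c("V", "J")) {
    ids <- vapply(results, function(r) r$model_id, integer(1))
    if (length(unique(ids)) > 1)
      stop("all subjects must be fitted with the same architecture")
    rows <- lapply(results, function(r) {
      ps <- posterior_summary(r, if (kind == "V") "V" else "J")
      setNames(ps$mean, ps$parameter)
    })
  } else {
    if (is.null(subjects))
      subjects <- vapply(results, function(d) as.character(d$subject),
                         character(1))
    if (is.null(groups))
      groups <- vapply(results, function(d) as.character(d$group),
                       character(1))
    rows <- lapply(results, function(d) {
      pk <- difference_wave_peaks(d, window)
      pk <- pk[pk$node != "mean", ]
      setNames(pk$amplitude, pk$node)
    })
  }
  feat <- do.call(rbind, rows)
  if (anyDuplicated(colnames(feat))) stop("duplicate feature columns")
  if (any(!is.finite(feat))) stop("missing or non-finite feature values")
  tab <- data.frame(subject = subjects, group = groups, feat,
                    check.names = FALSE, row.names = NULL)
  if (min(table(groups)) < 2) stop("need at least 2 subjects per group")
  structure(tab, feature_set = kind, class = c("feature_table", "data.frame"))
}

#' Leave-one-out permutation SVM classification
#'
#' Per permutation, one uniformly drawn subject is held out (with
#' replacement across permutations), a support vector machine is trained on
#' the remaining subjects with features z-scored by training-fold
#' statistics, and the held-out prediction is recorded. Confusion counts
#' are expressed as percentages of permutations; patients are the positive
#' class.
#'
#' @param table A [assemble_features()] table.
#' @param n_perm Number of permutations.
#' @param seed Seed for the held-out draws.
#' @param svm_config List: `kernel` (default linear), `cost` (default 1),
#'   `class_weights` (optional, `"inverse"` weights each training fold's
#'   classes by inverse frequency so the held-out class is not disfavoured
#'   by the fold's one-subject imbalance).
#' @param positive Label of the positive class.
#' @param null_permute Permutation-test null: re-permute the group labels
#'   uniformly at random before every iteration, so the held-out label is
#'   independent of the features. Use together with inverse class weights
#'   to measure the chance level; plain leave-one-out on a single fixed
#'   label assignment sits systematically below 50% on null data
#'   (anti-learning), because the held-out subject's own-class statistics
#'   are computed without it.
#' @return Object of class `classification_report` with TP/TN/FP/FN (% of
#'   permutations), accuracy, PPV, NPV, sensitivity, specificity, the
#'   per-permutation predictions, n_perm and seed.
#' @export
loo_svm_permutation <- function(table, n_perm = 1000, seed = 1,
                                svm_config = list(kernel = "linear", cost = 1),
                                positive = "patient", null_permute = FALSE) {
  stopifnot(n_perm >= 1)
  X <- as.matrix(table[, setdiff(names(table), c("subject", "group")),
                       drop = FALSE])
  y <- as.character(table$group)
  if (!positive %in% y) positive <- sort(unique(y))[2]
  n <- nrow(X)
  kernel <- svm_config$kernel %||% "linear"
  cost <- svm_config$cost %||% 1
  balanced <- identical(svm_config$class_weights, "inverse")

  set.seed(seed)
  held <- sample.int(n, n_perm, replace = TRUE)
  truth <- pred <- character(n_perm)
  redraws <- 0L
  for (p in seq_len(n_perm)) {
    yp <- if (null_permute) sample(y) else y
    i <- held[p]
    while (length(unique(yp[-i])) < 2) { # degenerate training fold
      redraws <- redraws + 1L
      i <- sample.int(n, 1)
    }
    Xtr <- X[-i, , drop = FALSE]
    mu <- colMeans(Xtr)
    sdv <- apply(Xtr, 2, sd)
    sdv[sdv == 0] <- 1
    Xtr <- scale(Xtr, mu, sdv)
    Xte <- matrix((X[i, ] - mu) / sdv, 1)
    cw <- NULL
    if (balanced) {
      # inverse-frequency weights of the training fold, so the held-out
      # class is not disfavoured by the fold's 1-subject imbalance
      tb <- table(yp[-i])
      cw <- setNames(sum(tb) / (length(tb) * as.numeric(tb)), names(tb))
    }
    fit <- e1071::svm(Xtr, factor(yp[-i]), kernel = kernel, cost = cost,
                      scale = FALSE, class.weights = cw)
    truth[p] <- yp[i]
    pred[p] <- as.character(predict(fit, Xte))
  }

  tp <- sum(truth == positive & pred == positive)
  tn <- sum(truth != positive & pred != positive)
  fp <- sum(truth != positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  pct <- function(x) 100 * x / n_perm
  structure(list(
    feature_set = attr(table, "feature_set"),
    TP = pct(tp), TN = pct(tn), FP = pct(fp), FN = pct(fn),
    accuracy = pct(tp + tn),
    PPV = 100 * tp / (tp + fp), NPV = 100 * tn / (tn + fn),
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp),
    predictions = data.frame(held_out = held, truth = truth, pred = pred),
    n_perm = n_perm, seed = seed, redraws = redraws,
    positive = positive), class = "classification_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Comparative classification table across feature sets
#'
#' @param reports List of [loo_svm_permutation()] reports.
#' @return Data frame in the conventional layout: feature set, Correct (%),
#'   TP, TN, FP, FN (% of permutations), PPV, NPV, Sens, Spec, n_perm,
#'   seed.
#' @export
classification_report <- function(reports) {
  if (length(reports) == 0) stop("need at least one report")
  if (inherits(reports, "classification_report")) reports <- list(reports)
  do.call(rbind, lapply(reports, function(r) {
    data.frame(features = r$feature_set %||% NA,
               correct_pct = r$accuracy,
               TP = r$TP, TN = r$TN, FP = r$FP, FN = r$FN,
               PPV = r$PPV, NPV = r$NPV,
               sens = r$sensitivity, spec = r$specificity,
               n_perm = r$n_perm, seed = r$seed, row.names = NULL)
  }))
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("Leave-one-out SVM (%s features, %d permutations, seed %d)\n",
              x$feature_set %||% "?", x$n_perm, x$seed))
  cat(sprintf("  accuracy %.1f%%  TP %.1f  TN %.1f  FP %.1f  FN %.1f\n",
              x$accuracy, x$TP, x$TN, x$FP, x$FN))
  cat(sprintf("  PPV %.1f  NPV %.1f  sensitivity %.1f  specificity %.1f\n",
              x$PPV, x$NPV, x$sensitivity, x$specificity))
  invisible(x)
}
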